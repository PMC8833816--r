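# fixture builders: every fixture is constructed in code

# one fully valid record; override any field by name
make_record <- function(patient_id = "P001", age = 45, menopausal = "pre",
                        ca125 = 30, he4 = 50, histology = "benign",
                        expert_call = NA_character_, ovarian = 1L,
                        site = "cancer_centre", figo_stage = NA_character_,
                        colour_score = 2L, ...) {
  rec <- data.frame(
    patient_id = patient_id, age = age, menopausal = menopausal,
    ca125 = ca125, he4 = he4,
    b_unilocular = 0L, b_solid_lt7mm = 0L, b_acoustic_shadows = 0L,
    b_smooth_multiloc_lt100 = 0L, b_no_flow = 0L,
    m_irregular_solid = 0L, m_ascites = 0L, m_papillary_ge4 = 0L,
    m_irregular_multiloc_solid_ge100 = 0L, m_strong_flow = 0L,
    colour_score = colour_score,
    rmi_multilocular = 0L, rmi_solid_areas = 0L, rmi_metastases = 0L,
    rmi_ascites = 0L, rmi_bilateral = 0L,
    expert_call = expert_call, histology = histology, ovarian = ovarian,
    site = site, figo_stage = figo_stage, stringsAsFactors = FALSE)
  over <- list(...)
  for (f in names(over)) rec[[f]] <- over[[f]]
  rec
}

make_cohort <- function(...) {
  recs <- list(...)
  as_triage_cohort(do.call(rbind, recs), provenance = "test fixture")
}

# all flag combinations consistent with the colour-score coupling:
# 8 free feature flags x colour scores 1-4 (flow flags derived)
enumerate_exams <- function() {
  free_b <- c("b_unilocular", "b_solid_lt7mm", "b_acoustic_shadows",
              "b_smooth_multiloc_lt100")
  free_m <- c("m_irregular_solid", "m_ascites", "m_papillary_ge4",
              "m_irregular_multiloc_solid_ge100")
  grid <- expand.grid(rep(list(0:1), 8), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- c(free_b, free_m)
  grid <- grid[rep(seq_len(nrow(grid)), each = 4), ]
  grid$colour_score <- rep(1:4, times = 256)
  grid$b_no_flow <- as.integer(grid$colour_score == 1)
  grid$m_strong_flow <- as.integer(grid$colour_score == 4)
  rownames(grid) <- NULL
  grid
}
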