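#' Default synthetic-cohort parameters
#'
#' Parameterises a cohort generator that emulates the marginal structure of
#' the multicentre pelvic-mass study the package defaults are calibrated to:
#' roughly half the women recruited at a cancer centre where about a third
#' of masses are malignant (including borderline tumours) against under a
#' tenth at general units (overall prevalence about 21%), 69% premenopausal,
#' an inconclusive simple-rules rate near 25% with about 31% malignancy
#' among the inconclusive masses, simple-rules sensitivity/specificity on
#' conclusive masses near 81%/97%, and an expert assessor operating at
#' 81% sensitivity and 71.7% specificity.
#'
#' Structure of the model (a deliberate simplification, not a claim about
#' tumour biology): given the truth class (benign / borderline / invasive
#' malignant), ultrasound features are independent Bernoulli draws except
#' that the two flow features derive from a single four-level colour score
#' and the RMI ascites flag equals the IOTA ascites feature; serum CA125
#' and HE4 are independent log-normals given class and menopausal status;
#' the expert call is correct with class-specific probability.  Borderline
#' tumours get attenuated feature and marker separation, which yields the
#' characteristically poor borderline sensitivity of all strategies.
#'
#' @param n default cohort size.
#' @param seed RNG seed stored with the parameters (optional).
#' @return a `generator_params` list with components `site_mix` (cancer
#'   centre fraction and site-specific prevalence), `prevalence` (used when
#'   `site_mix` is `NULL`), `borderline_frac`, `premenopausal_frac`,
#'   `nonovarian_frac`, `expert_sens`, `expert_spec`, `stage_dist`,
#'   `feature_probs` (per truth class: colour-score distribution, the four
#'   non-flow B-features, four non-flow M-features, and the four RMI
#'   features other than ascites) and `marker_dists` (log-normal meanlog /
#'   sdlog per class and menopausal status).
#' @export
default_params <- function(n = 690, seed = NULL) {
  bnames <- setdiff(B_FEATURES, "b_no_flow")
  mnames <- setdiff(M_FEATURES, "m_strong_flow")
  rnames <- setdiff(RMI_FEATURES, "rmi_ascites")
  fp <- function(colour, b, m, rmi)
    list(colour = colour, b = stats::setNames(b, bnames),
         m = stats::setNames(m, mnames), rmi = stats::setNames(rmi, rnames))
  md <- function(ca_pre, ca_post, he4_pre, he4_post)
    list(ca125 = list(pre = c(meanlog = ca_pre[1], sdlog = ca_pre[2]),
                      post = c(meanlog = ca_post[1], sdlog = ca_post[2])),
         he4 = list(pre = c(meanlog = he4_pre[1], sdlog = he4_pre[2]),
                    post = c(meanlog = he4_post[1], sdlog = he4_post[2])))
  params <- list(
    n = as.integer(n), seed = seed,
    site_mix = list(p_cancer_centre = 341 / 690,
                    prevalence_cancer_centre = 0.328,
                    prevalence_general = 0.086),
    prevalence = 0.206,
    borderline_frac = 36 / 179,
    premenopausal_frac = 0.693,
    nonovarian_frac = 50 / 690,
    expert_sens = 0.81, expert_spec = 0.717,
    stage_dist = c(I = 51, II = 15, III = 25, IV = 12, unstaged = 11) / 114,
    feature_probs = list(
      benign = fp(colour = c(0.38, 0.44, 0.16, 0.02),
                  b = rep(0.26, 4), m = rep(0.015, 4),
                  rmi = c(0.30, 0.12, 0.005, 0.10)),
      borderline = fp(colour = c(0.15, 0.40, 0.30, 0.15),
                      b = rep(0.15, 4), m = rep(0.12, 4),
                      rmi = c(0.45, 0.35, 0.02, 0.15)),
      malignant = fp(colour = c(0.05, 0.35, 0.34, 0.26),
                     b = rep(0.06, 4), m = rep(0.23, 4),
                     rmi = c(0.45, 0.70, 0.25, 0.30))),
    marker_dists = list(
      benign = md(c(3.40, 1.0), c(3.00, 0.9), c(3.55, 0.30), c(4.00, 0.35)),
      borderline = md(c(4.20, 1.1), c(4.20, 1.1), c(3.70, 0.5), c(4.10, 0.5)),
      malignant = md(c(5.50, 1.4), c(5.70, 1.4), c(4.90, 1.0), c(5.30, 1.0))))
  class(params) <- "generator_params"
  validate_generator_params(params)
  params
}

#' Validate generator parameters
#'
#' @param params a `generator_params` list.
#' @return `params` invisibly; errors name the offending component.
#' @export
validate_generator_params <- function(params) {
  prob <- function(x, what) {
    if (any(is.na(x)) || any(x < 0) || any(x > 1))
      stopf("%s must be probabilities in [0, 1]", what)
  }
  prob(params$prevalence, "prevalence")
  prob(params$borderline_frac, "borderline_frac")
  prob(params$premenopausal_frac, "premenopausal_frac")
  prob(params$nonovarian_frac, "nonovarian_frac")
  prob(params$expert_sens, "expert_sens")
  prob(params$expert_spec, "expert_spec")
  prob(params$stage_dist, "stage_dist")
  if (abs(sum(params$stage_dist) - 1) > 1e-8)
    stopf("stage_dist must sum to 1")
  if (!is.null(params$site_mix)) {
    prob(unlist(params$site_mix), "site_mix")
  }
  for (cl in names(params$feature_probs)) {
    fpc <- params$feature_probs[[cl]]
    prob(fpc$colour, sprintf("feature_probs$%s$colour", cl))
    if (length(fpc$colour) != 4 || abs(sum(fpc$colour) - 1) > 1e-8)
      stopf("feature_probs$%s$colour must be 4 probabilities summing to 1",
            cl)
    prob(fpc$b, sprintf("feature_probs$%s$b", cl))
    prob(fpc$m, sprintf("feature_probs$%s$m", cl))
    prob(fpc$rmi, sprintf("feature_probs$%s$rmi", cl))
  }
  for (cl in names(params$marker_dists)) {
    for (mk in c("ca125", "he4")) {
      for (mn in c("pre", "post")) {
        d <- params$marker_dists[[cl]][[mk]][[mn]]
        if (!is.numeric(d) || length(d) != 2 || !all(is.finite(d)) ||
              d[2] < 0)
          stopf("marker_dists$%s$%s$%s must be c(meanlog, sdlog >= 0)",
                cl, mk, mn)
      }
    }
  }
  invisible(params)
}

# invert a per-record categorical draw from one uniform, given a probability
# matrix with one row per class (keeps the RNG stream one-draw-per-field)
draw_categorical <- function(u, probmat, classidx) {
  cum <- t(apply(probmat, 1, cumsum))
  out <- rep(1L, length(u))
  for (k in seq_len(ncol(probmat) - 1))
    out <- out + (u > cum[classidx, k])
  out
}

#' Generate a synthetic triage cohort
#'
#' Draws `n` independent records under a [default_params()]-style model.
#' Draws are made in a fixed field order (site, truth class, borderline
#' split, menopause, age, colour score, B-features, M-features, RMI
#' features, CA125, HE4, expert correctness, FIGO stage, ovarian origin),
#' one block of `n` uniforms per field, so a given seed pins every field
#' even if later fields are added to the model.  The expert call is only
#' recorded for records whose simple-rules result is inconclusive, as in
#' the study design the generator emulates.
#'
#' @param params a `generator_params` list.
#' @param n cohort size (defaults to `params$n`).
#' @param seed RNG seed (defaults to `params$seed`; `NULL` leaves the RNG
#'   state alone).
#' @return a `triage_cohort` of `n` records.
#' @export
generate_cohort <- function(params = default_params(), n = params$n,
                            seed = params$seed) {
  validate_generator_params(params)
  if (!is.null(seed)) set.seed(seed)
  classes <- c("benign", "borderline", "malignant")

  site <- ifelse(stats::runif(n) < (params$site_mix$p_cancer_centre %||% 0),
                 "cancer_centre", "general_unit")
  prev <- if (is.null(params$site_mix)) rep(params$prevalence, n) else
    ifelse(site == "cancer_centre",
           params$site_mix$prevalence_cancer_centre,
           params$site_mix$prevalence_general)
  truth <- stats::runif(n) < prev
  borderline <- truth & stats::runif(n) < params$borderline_frac
  histology <- ifelse(!truth, "benign",
                      ifelse(borderline, "borderline", "malignant"))
  cls <- match(histology, classes)

  menopausal <- ifelse(stats::runif(n) < params$premenopausal_frac,
                       "pre", "post")
  u_age <- stats::runif(n)
  age <- ifelse(menopausal == "pre", 20 + floor(u_age * 32),
                52 + floor(u_age * 33))

  colour_mat <- do.call(rbind, lapply(params$feature_probs,
                                      function(f) f$colour))
  colour <- draw_categorical(stats::runif(n), colour_mat, cls)

  draw_flags <- function(which) {
    pm <- do.call(rbind, lapply(params$feature_probs, function(f) f[[which]]))
    flags <- vapply(seq_len(ncol(pm)), function(j)
      as.integer(stats::runif(n) < pm[cls, j]), integer(n))
    flags <- matrix(flags, nrow = n, ncol = ncol(pm),
                    dimnames = list(NULL, colnames(pm)))
    as.data.frame(flags)
  }
  bflags <- draw_flags("b")
  mflags <- draw_flags("m")
  rflags <- draw_flags("rmi")

  draw_marker <- function(marker) {
    pars <- array(NA_real_, c(3, 2, 2))
    for (i in 1:3) for (j in 1:2)
      pars[i, j, ] <- params$marker_dists[[classes[i]]][[marker]][[
        c("pre", "post")[j]]]
    mi <- cbind(cls, ifelse(menopausal == "pre", 1L, 2L))
    stats::qlnorm(stats::runif(n),
                  meanlog = pars[cbind(mi, rep(1L, n))],
                  sdlog = pars[cbind(mi, rep(2L, n))])
  }
  ca125 <- draw_marker("ca125")
  he4 <- draw_marker("he4")

  p_correct <- ifelse(truth, params$expert_sens, params$expert_spec)
  expert_correct <- stats::runif(n) < p_correct
  expert_call <- ifelse(truth == expert_correct, "malignant", "benign")

  stage_mat <- matrix(rep(params$stage_dist, each = 1), nrow = 1)
  figo <- names(params$stage_dist)[draw_categorical(
    stats::runif(n), stage_mat, rep(1L, n))]
  figo[!truth] <- NA_character_

  ovarian <- as.integer(stats::runif(n) >= params$nonovarian_frac)

  data <- data.frame(
    patient_id = sprintf("S%05d", seq_len(n)),
    age = as.numeric(age), menopausal = menopausal,
    ca125 = ca125, he4 = he4,
    b_unilocular = bflags$b_unilocular,
    b_solid_lt7mm = bflags$b_solid_lt7mm,
    b_acoustic_shadows = bflags$b_acoustic_shadows,
    b_smooth_multiloc_lt100 = bflags$b_smooth_multiloc_lt100,
    b_no_flow = as.integer(colour == 1),
    m_irregular_solid = mflags$m_irregular_solid,
    m_ascites = mflags$m_ascites,
    m_papillary_ge4 = mflags$m_papillary_ge4,
    m_irregular_multiloc_solid_ge100 =
      mflags$m_irregular_multiloc_solid_ge100,
    m_strong_flow = as.integer(colour == 4),
    colour_score = as.integer(colour),
    rmi_multilocular = rflags$rmi_multilocular,
    rmi_solid_areas = rflags$rmi_solid_areas,
    rmi_metastases = rflags$rmi_metastases,
    rmi_ascites = mflags$m_ascites,
    rmi_bilateral = rflags$rmi_bilateral,
    expert_call = expert_call,
    histology = histology, ovarian = ovarian, site = site,
    figo_stage = figo, stringsAsFactors = FALSE)

  # expert assessment only performed where the simple rules are inconclusive
  if (n > 0) {
    concl <- classify_iota(data)$call != "inconclusive"
    data$expert_call[concl] <- NA_character_
  }
  as_triage_cohort(
    data,
    provenance = sprintf("generator(seed=%s, n=%d)",
                         if (is.null(seed)) "NULL" else seed, n))
}

# ---- closed-form analytics of the generator ------------------------------

# IOTA call probabilities for one class, conditional on ascites status
iota_probs_given_ascites <- function(fpc, a) {
  q <- fpc$colour
  pB4 <- 1 - prod(1 - fpc$b)
  m_other <- fpc$m[setdiff(names(fpc$m), "m_ascites")]
  pM3 <- 1 - prod(1 - m_other)
  Ma <- if (a) 1 else pM3                 # P(non-flow M present | ascites)
  mal <- (q[4] + (q[2] + q[3]) * Ma) * (1 - pB4)
  ben <- (q[1] + (q[2] + q[3]) * pB4) * (1 - Ma)
  c(malignant = mal, benign = ben, inconclusive = 1 - mal - ben)
}

# distribution of the RMI ultrasound score for one class given ascites
u_dist_given_ascites <- function(fpc, a) {
  conv <- 1
  for (r in fpc$rmi) conv <- c(conv * (1 - r), 0) + c(0, conv * r)
  count0 <- conv[1]; count1 <- conv[2]
  if (a) c(u0 = 0, u1 = count0, u3 = 1 - count0)
  else c(u0 = count0, u1 = count1, u3 = 1 - count0 - count1)
}

lnorm_survival <- function(x, par) {
  if (par[2] == 0) as.numeric(exp(par[1]) >= x)
  else stats::plnorm(x, par[1], par[2], lower.tail = FALSE)
}

# P(ROMA high) for one class and menopausal group: the predictive index is
# normal because both log-markers are
roma_high_prob <- function(md, meno, thresholds) {
  cf <- ROMA_COEF[[meno]]
  cut <- if (meno == "pre") thresholds$roma_pre else thresholds$roma_post
  pi_cut <- stats::qlogis(cut / 100)
  he4 <- md$he4[[meno]]; ca <- md$ca125[[meno]]
  mu <- cf["intercept"] + cf["he4"] * he4[1] + cf["ca125"] * ca[1]
  sd <- sqrt(cf["he4"]^2 * he4[2]^2 + cf["ca125"]^2 * ca[2]^2)
  if (sd == 0) return(as.numeric(mu >= pi_cut))
  unname(stats::pnorm(pi_cut, mu, sd, lower.tail = FALSE))
}

rmi_high_prob_given_ascites <- function(fpc, md, meno, a, thresholds) {
  u <- u_dist_given_ascites(fpc, a)
  m <- if (meno == "pre") 1 else 3
  ca <- md$ca125[[meno]]
  unname(u["u1"] * lnorm_survival(thresholds$rmi / m, ca) +
           u["u3"] * lnorm_survival(thresholds$rmi / (3 * m), ca))
}

#' Expected operating points of every strategy under the generator
#'
#' Closed-form sensitivity and specificity of each triage strategy under a
#' generator parameterisation, exploiting the generator's conditional
#' independence structure: feature flags are independent given class except
#' through the colour score and the shared ascites flag (which couples the
#' IOTA call to the RMI ultrasound score and is integrated out explicitly),
#' markers are independent of features given class and menopausal status,
#' and the ROMA predictive index is normal because both log-markers are.
#' `IOTA_ONLY` operating points are conditional on a conclusive
#' simple-rules result; all others refer to the full population.
#'
#' @param params a `generator_params` list.
#' @param thresholds a [triage_thresholds()] object.
#' @return data frame with columns `strategy`, `sensitivity`,
#'   `specificity`.
#' @export
analytic_operating_points <- function(params = default_params(),
                                      thresholds = triage_thresholds()) {
  validate_generator_params(params)
  classes <- c("benign", "borderline", "malignant")
  w_pre <- params$premenopausal_frac
  menos <- c(pre = w_pre, post = 1 - w_pre)

  high <- matrix(NA_real_, nrow = 6, ncol = 3,
                 dimnames = list(triage_strategies(), classes))
  iota_mal <- iota_ben <- iota_incl <- stats::setNames(numeric(3), classes)

  for (cl in classes) {
    fpc <- params$feature_probs[[cl]]
    md <- params$marker_dists[[cl]]
    pa <- unname(fpc$m["m_ascites"])
    asc <- c(`0` = 1 - pa, `1` = pa)
    io <- lapply(c(0, 1), function(a) iota_probs_given_ascites(fpc, a))
    iota_mal[cl] <- asc[1] * io[[1]]["malignant"] + asc[2] * io[[2]]["malignant"]
    iota_ben[cl] <- asc[1] * io[[1]]["benign"] + asc[2] * io[[2]]["benign"]
    iota_incl[cl] <- 1 - iota_mal[cl] - iota_ben[cl]

    expert_high <- if (cl == "benign") 1 - params$expert_spec else
      params$expert_sens
    high["IOTA_EXPERT", cl] <- iota_mal[cl] + iota_incl[cl] * expert_high

    roma_h <- sum(vapply(names(menos), function(mn)
      menos[mn] * roma_high_prob(md, mn, thresholds), numeric(1)))
    high["ROMA_ALONE", cl] <- roma_h
    high["IOTA_ROMA", cl] <- iota_mal[cl] + iota_incl[cl] * roma_h

    rmi_h <- iota_rmi_h <- 0
    for (mn in names(menos)) {
      for (ai in 1:2) {
        a <- ai - 1
        rh <- rmi_high_prob_given_ascites(fpc, md, mn, a, thresholds)
        rmi_h <- rmi_h + menos[mn] * asc[ai] * rh
        iota_rmi_h <- iota_rmi_h + menos[mn] * asc[ai] *
          (io[[ai]]["malignant"] + io[[ai]]["inconclusive"] * rh)
      }
    }
    high["RMI_ALONE", cl] <- rmi_h
    high["IOTA_RMI", cl] <- iota_rmi_h
  }

  bf <- params$borderline_frac
  sens <- (1 - bf) * high[, "malignant"] + bf * high[, "borderline"]
  spec <- 1 - high[, "benign"]
  # IOTA_ONLY is conditional on a conclusive result
  sens["IOTA_ONLY"] <-
    ((1 - bf) * iota_mal["malignant"] + bf * iota_mal["borderline"]) /
    ((1 - bf) * (1 - iota_incl["malignant"]) +
       bf * (1 - iota_incl["borderline"]))
  spec["IOTA_ONLY"] <- iota_ben["benign"] / (1 - iota_incl["benign"])

  data.frame(strategy = triage_strategies(),
             sensitivity = unname(sens[triage_strategies()]),
             specificity = unname(spec[triage_strategies()]),
             stringsAsFactors = FALSE)
}

#' Expected cohort marginals under the generator
#'
#' Closed-form population fractions implied by a parameterisation: overall
#' malignancy prevalence (site-mix weighted when site-specific prevalence
#' overrides are present), premenopausal fraction, the inconclusive
#' simple-rules rate, and the malignancy fraction among inconclusive
#' masses.
#'
#' @param params a `generator_params` list.
#' @return named numeric vector with elements `prevalence`,
#'   `premenopausal_frac`, `inconclusive_rate`,
#'   `malignant_among_inconclusive`.
#' @export
analytic_marginals <- function(params = default_params()) {
  validate_generator_params(params)
  prev <- if (is.null(params$site_mix)) params$prevalence else
    params$site_mix$p_cancer_centre * params$site_mix$prevalence_cancer_centre +
      (1 - params$site_mix$p_cancer_centre) * params$site_mix$prevalence_general
  bf <- params$borderline_frac
  incl <- vapply(c("benign", "borderline", "malignant"), function(cl) {
    fpc <- params$feature_probs[[cl]]
    pa <- unname(fpc$m["m_ascites"])
    (1 - pa) * iota_probs_given_ascites(fpc, 0)["inconclusive"] +
      pa * iota_probs_given_ascites(fpc, 1)["inconclusive"]
  }, numeric(1))
  names(incl) <- c("benign", "borderline", "malignant")
  weights <- c(benign = 1 - prev, borderline = prev * bf,
               malignant = prev * (1 - bf))
  incl_rate <- sum(weights * incl)
  mal_among_incl <- sum(weights[c("borderline", "malignant")] *
                          incl[c("borderline", "malignant")]) / incl_rate
  c(prevalence = prev, premenopausal_frac = params$premenopausal_frac,
    inconclusive_rate = unname(incl_rate),
    malignant_among_inconclusive = unname(mal_among_incl))
}
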