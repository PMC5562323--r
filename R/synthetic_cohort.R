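# Synthetic cirrhosis cohorts.
#
# A single latent severity variable Z ~ N(0,1) (truncated to its central
# 99.8% to keep HVPG in a clinical range) drives HVPG through a monotone
# piecewise-linear map anchored so that P(HVPG >= 10) and P(HVPG >= 12)
# equal the configured CSPH/SPH prevalences exactly. Labs are drawn
# conditional on the CSPH stratum with the stratum means/SDs of the study
# population; severity_coupling reallocates part of the within-stratum
# variance onto Z (signed per lab) without shifting the stratum moments,
# which produces the observed direction of the multivariate associations
# (AST positive, PLT and albumin negative with HVPG grade). Right-skewed
# labs are drawn lognormal with moment-matched mean/SD; symmetric labs are
# normal, resampled (not clamped) while non-positive.

.default_lab_strata <- function() {
  # per lab: mean/sd without CSPH, mean/sd with CSPH (study Table-1 scales),
  # transform, and the sign of the severity coupling
  lab <- function(m0, s0, m1, s1, transform, sign)
    list(mean_no_csph = m0, sd_no_csph = s0, mean_csph = m1, sd_csph = s1,
         transform = transform, sign = sign)
  list(
    age             = lab(53.74, 10.23, 52.24, 10.50, "identity", 0),
    ast             = lab(32.38, 13.91, 51.15, 36.83, "log", +1),
    alt             = lab(24.86, 10.79, 43.01, 44.45, "log", +1),
    ggt             = lab(56.55, 82.76, 62.23, 67.47, "log", +1),
    albumin         = lab(36.10, 7.23, 32.55, 6.73, "identity", -1),
    bilirubin_total = lab(23.06, 10.74, 33.78, 46.78, "log", +1),
    cholesterol     = lab(3.82, 0.99, 3.81, 1.31, "identity", 0),
    plt             = lab(130.64, 90.30, 91.21, 60.92, "identity", -1),
    inr             = lab(1.15, 0.11, 1.27, 0.17, "identity", +1))
}

.default_categoricals <- function() {
  # conditional frequencies (without CSPH n = 50; with CSPH n = 188)
  list(
    etiology = list(
      levels = c("HBV", "HCV", "alcohol", "PBC", "autoimmune",
                 "cryptogenic"),
      no_csph = c(19, 0, 3, 1, 4, 23) / 50,
      csph = c(103, 13, 17, 6, 6, 43) / 188),
    child_pugh = list(
      levels = c("A", "B", "C"),
      no_csph = c(39, 11, 0) / 50,
      csph = c(71, 93, 24) / 188),
    ascites = list(
      levels = c("none", "mild", "moderate_severe"),
      no_csph = c(34, 15, 1) / 50,
      csph = c(77, 52, 59) / 188),
    sex = list(
      levels = c("male", "female"),
      no_csph = c(31, 19) / 50,
      csph = c(130, 58) / 188))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study population's stratified baseline
#' characteristics: CSPH prevalence 0.79, SPH prevalence 0.685, HVPG range
#' 2-35 mmHg, and per-stratum lab means/SDs and categorical frequencies.
#'
#' @param n cohort size (>= 0).
#' @param seed integer RNG seed.
#' @param p_csph target P(HVPG >= 10).
#' @param p_sph target P(HVPG >= 12); must not exceed \code{p_csph}.
#' @param hvpg_range length-2 numeric, attainable HVPG interval (mmHg).
#' @param severity_coupling within-stratum lab-severity correlation
#'   magnitude, in [0, 1).
#' @param lab_strata,categoricals optional overrides of the default
#'   distribution tables (same structure as the defaults).
#' @return object of class \code{ph_gen_config}.
#' @export
generator_config <- function(n = 238, seed = 1L, p_csph = 0.79,
                             p_sph = 0.685, hvpg_range = c(2, 35),
                             severity_coupling = 0.3,
                             lab_strata = .default_lab_strata(),
                             categoricals = .default_categoricals()) {
  if (n < 0) stop("n must be >= 0")
  if (p_csph < 0 || p_csph > 1 || p_sph < 0 || p_sph > 1)
    stop("prevalences must be in [0, 1]")
  if (p_sph > p_csph) stop("p_sph cannot exceed p_csph")
  if (length(hvpg_range) != 2 || hvpg_range[1] >= 10 || hvpg_range[2] <= 12)
    stop("hvpg_range must straddle the 10 and 12 mmHg thresholds")
  if (severity_coupling < 0 || severity_coupling >= 1)
    stop("severity_coupling must be in [0, 1)")
  for (nm in names(lab_strata)) {
    lab <- lab_strata[[nm]]
    if (lab$sd_no_csph <= 0 || lab$sd_csph <= 0)
      stop("lab SDs must be > 0 (", nm, ")")
  }
  for (nm in names(categoricals)) {
    cc <- categoricals[[nm]]
    for (p in list(cc$no_csph, cc$csph))
      if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
        stop("categorical probabilities for ", nm, " must sum to 1")
  }
  structure(list(n = n, seed = as.integer(seed), p_csph = p_csph,
                 p_sph = p_sph, hvpg_range = hvpg_range,
                 severity_coupling = severity_coupling,
                 lab_strata = lab_strata, categoricals = categoricals,
                 u_trunc = c(0.001, 0.999)),
            class = "ph_gen_config")
}

# conditional mean/sd of Z ~ N(0,1) restricted to qnorm(ul) < Z < qnorm(ur)
.truncnorm_moments <- function(ul, ur) {
  l <- stats::qnorm(ul); r <- stats::qnorm(ur)
  p <- ur - ul
  m <- (stats::dnorm(l) - stats::dnorm(r)) / p
  v <- 1 + (l * stats::dnorm(l) - r * stats::dnorm(r)) / p - m^2
  c(mean = m, sd = sqrt(v))
}

#' Generate a synthetic cirrhosis cohort
#'
#' Deterministic given the config's seed; all records pass cohort
#' validation; labs are strictly positive and HVPG lies inside the
#' configured range.
#'
#' @param config \code{ph_gen_config} from \code{\link{generator_config}}.
#' @return \code{ph_cohort} with an \code{hvpg} column.
#' @export
generate_cohort <- function(config = generator_config()) {
  stopifnot(inherits(config, "ph_gen_config"))
  n <- config$n
  if (n == 0L)
    return(as_cohort(
      data.frame(id = character(), age = numeric(), sex = character(),
                 stringsAsFactors = FALSE)[0, ],
      provenance = "synthetic"))
  set.seed(config$seed)
  a <- config$u_trunc[1]; b <- config$u_trunc[2]

  u <- stats::runif(n, a, b)
  z <- stats::qnorm(u)
  # anchors in probability space so exceedance targets hold exactly under
  # the truncation
  u10 <- b - config$p_csph * (b - a)
  u12 <- b - config$p_sph * (b - a)
  zk <- stats::qnorm(c(a, u10, u12, b))
  hk <- c(config$hvpg_range[1], 10, 12, config$hvpg_range[2])
  hvpg <- stats::approx(zk, hk, xout = z, rule = 2)$y
  csph <- hvpg >= 10

  # conditional moments of z within each stratum (for coupling that leaves
  # stratum lab moments unchanged)
  mom_no <- .truncnorm_moments(a, u10)
  mom_cs <- .truncnorm_moments(u10, b)
  z_std <- ifelse(csph, (z - mom_cs["mean"]) / mom_cs["sd"],
                  (z - mom_no["mean"]) / mom_no["sd"])

  rho <- config$severity_coupling
  draw_lab <- function(lab) {
    m <- ifelse(csph, lab$mean_csph, lab$mean_no_csph)
    s <- ifelse(csph, lab$sd_csph, lab$sd_no_csph)
    r <- rho * lab$sign
    eps <- stats::rnorm(n)
    e <- sqrt(1 - r^2) * eps + r * z_std
    if (lab$transform == "log") {
      sig2 <- log(1 + (s / m)^2)
      exp(log(m) - sig2 / 2 + sqrt(sig2) * e)
    } else {
      val <- m + s * e
      for (it in seq_len(1000)) {
        bad <- which(val <= 0)
        if (!length(bad)) break
        e_new <- sqrt(1 - r^2) * stats::rnorm(length(bad)) + r * z_std[bad]
        val[bad] <- m[bad] + s[bad] * e_new
      }
      pmax(val, 0.01)
    }
  }
  labs <- lapply(config$lab_strata, draw_lab)

  draw_cat <- function(cc) {
    probs <- rbind(cc$no_csph, cc$csph)[csph + 1, , drop = FALSE]
    cum <- t(apply(probs, 1, cumsum))
    u <- stats::runif(n)
    cc$levels[1L + rowSums(u > cum)]
  }
  cats <- lapply(config$categoricals, draw_cat)

  df <- data.frame(id = sprintf("S%05d", seq_len(n)),
                   age = labs$age, sex = cats$sex,
                   etiology = cats$etiology, child_pugh = cats$child_pugh,
                   ascites = cats$ascites,
                   ast = labs$ast, alt = labs$alt, ggt = labs$ggt,
                   albumin = labs$albumin,
                   bilirubin_total = labs$bilirubin_total,
                   cholesterol = labs$cholesterol, plt = labs$plt,
                   inr = labs$inr, hvpg = hvpg,
                   stringsAsFactors = FALSE)
  as_cohort(df, provenance = sprintf("synthetic(n=%d, seed=%d)", n,
                                     config$seed))
}

#' Stratified summary of a cohort (baseline-characteristics analogue)
#'
#' Means and SDs of every numeric variable overall and within the
#' CSPH/SPH strata, plus categorical percentages. SDs of single-record
#' strata are NA.
#'
#' @param cohort \code{ph_cohort} with an \code{hvpg} column.
#' @return list with data frames \code{numeric} and \code{categorical},
#'   both writable with \code{write.csv}.
#' @export
summarize_cohort <- function(cohort) {
  df <- as.data.frame(cohort)
  if (nrow(df) == 0L) stop("cohort is empty")
  if (all(is.na(df$hvpg))) stop("cohort has no HVPG values")
  cls <- classify_hvpg(df$hvpg)
  strata <- list(overall = rep(TRUE, nrow(df)),
                 no_csph = !cls$csph, csph = cls$csph,
                 no_sph = !cls$sph, sph = cls$sph)
  num_vars <- intersect(.cohort_numeric_cols, names(df))
  num <- do.call(rbind, lapply(num_vars, function(v) {
    row <- data.frame(variable = v, stringsAsFactors = FALSE)
    for (s in names(strata)) {
      x <- df[[v]][strata[[s]]]
      row[[paste0(s, "_mean")]] <- if (length(x)) mean(x, na.rm = TRUE)
        else NA_real_
      row[[paste0(s, "_sd")]] <- if (sum(!is.na(x)) > 1)
        stats::sd(x, na.rm = TRUE) else NA_real_
      row[[paste0(s, "_n")]] <- sum(!is.na(x))
    }
    row
  }))
  cat_vars <- c("sex", "etiology", "child_pugh", "ascites")
  cat_tab <- do.call(rbind, lapply(cat_vars, function(v) {
    if (!v %in% names(df)) return(NULL)
    levs <- sort(unique(stats::na.omit(df[[v]])))
    do.call(rbind, lapply(levs, function(lev) {
      row <- data.frame(variable = v, level = lev,
                        stringsAsFactors = FALSE)
      for (s in names(strata)) {
        x <- df[[v]][strata[[s]]]
        row[[paste0(s, "_pct")]] <- if (length(x))
          100 * mean(x == lev, na.rm = TRUE) else NA_real_
      }
      row
    }))
  }))
  list(numeric = num, categorical = cat_tab)
}
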