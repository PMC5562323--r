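# Brute-force oracles kept deliberately independent of the package's
# rank-based / placement-based implementations.

# pairwise Mann-Whitney AUC: loop over every (pos, neg) pair
oracle_auc <- function(pos, neg) {
  wins <- 0
  for (x in pos) for (y in neg)
    wins <- wins + (x > y) + 0.5 * (x == y)
  wins / (length(pos) * length(neg))
}

# trapezoidal area under the empirical ROC polygon in (1-spec, sens) space
oracle_trapezoid <- function(curve) {
  fpr <- 1 - curve$spec
  sens <- curve$sens
  o <- order(fpr, sens)
  fpr <- fpr[o]; sens <- sens[o]
  sum(diff(fpr) * (utils::head(sens, -1) + utils::tail(sens, -1)) / 2)
}

# exhaustive Youden search over every candidate cutoff (unique scores plus
# a sentinel), same tie-break rule: max J, then max sens, then min cutoff
oracle_youden <- function(pos, neg) {
  cands <- c(sort(unique(c(pos, neg))), max(c(pos, neg)) + 1)
  best <- NULL
  for (ct in cands) {
    sens <- mean(pos >= ct)
    spec <- mean(neg < ct)
    j <- sens + spec - 1
    if (is.null(best) || j > best$j + 1e-12 ||
        (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12))
      best <- list(cutoff = ct, j = j, sens = sens, spec = spec)
  }
  best
}

# DeLong covariance of two paired AUCs from first principles (placements
# recomputed with explicit loops)
oracle_paired_cov <- function(sa, sb, labels) {
  pos <- which(labels); neg <- which(!labels)
  m <- length(pos); n <- length(neg)
  place <- function(s) {
    v10 <- sapply(pos, function(i)
      mean((s[i] > s[neg]) + 0.5 * (s[i] == s[neg])))
    v01 <- sapply(neg, function(j)
      mean((s[pos] > s[j]) + 0.5 * (s[pos] == s[j])))
    list(v10 = v10, v01 = v01)
  }
  pa <- place(sa); pb <- place(sb)
  stats::cov(pa$v10, pb$v10) / m + stats::cov(pa$v01, pb$v01) / n
}

# a batch of random valid patient records on realistic lab scales
random_records <- function(n) {
  data.frame(
    id = sprintf("R%04d", seq_len(n)),
    age = runif(n, 18, 85),
    ast = runif(n, 10, 300),
    alt = runif(n, 8, 250),
    ggt = runif(n, 10, 400),
    albumin = runif(n, 20, 50),
    cholesterol = runif(n, 1.5, 8),
    plt = runif(n, 20, 400),
    inr = runif(n, 0.9, 2.5),
    stringsAsFactors = FALSE)
}
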