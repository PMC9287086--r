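# Independent oracles and in-code fixtures shared across the suite.

# Student-t quantile by density integration + root finding (independent of qt)
oracle_t_quantile <- function(p, df) {
  dens <- function(x) {
    gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + x^2 / df)^(-(df + 1) / 2)
  }
  stopifnot(p > 0.5)  # upper-tail quantiles only, as used by HR_PIR / DL
  cdf <- function(q) 0.5 + stats::integrate(dens, 0, q, rel.tol = 1e-12)$value
  stats::uniroot(function(q) cdf(q) - p, c(0, 200), tol = 1e-10)$root
}

# Brute-force isotopologue enumeration (independent of the convolution code)
oracle_isotope_pattern <- function(formula_text, threshold = 0.001,
                                   merge_da = 0.01) {
  iso_tab <- list(
    H = list(m = c(1.00782503207, 2.0141017781), p = c(0.999885, 0.000115)),
    C = list(m = c(12.0, 13.0033548378), p = c(0.9893, 0.0107)),
    N = list(m = c(14.0030740048, 15.0001088989), p = c(0.99636, 0.00364)),
    O = list(m = c(15.9949146196, 16.9991317565, 17.9991596129),
             p = c(0.99757, 0.00038, 0.00205)),
    F = list(m = 18.9984031627, p = 1),
    S = list(m = c(31.9720711744, 32.9714589098, 33.9678670040, 35.9670807100),
             p = c(0.9499, 0.0075, 0.0425, 0.0001)),
    Cl = list(m = c(34.9688526820, 36.9659026020), p = c(0.7576, 0.2424)))
  f <- parse_formula(formula_text)
  compositions <- function(n, k) {
    if (k == 1) return(matrix(n, 1, 1))
    out <- NULL
    for (i in 0:n) out <- rbind(out, cbind(i, compositions(n - i, k - 1)))
    out
  }
  per_elem <- lapply(names(f$counts), function(sym) {
    iso <- iso_tab[[sym]]
    n <- f$counts[[sym]]
    cm <- compositions(n, length(iso$m))
    mass <- drop(cm %*% iso$m)
    logp <- lgamma(n + 1) - rowSums(lgamma(cm + 1)) +
      drop(cm %*% ifelse(iso$p > 0, log(iso$p), -Inf))
    data.frame(mass = mass, p = exp(logp))
  })
  d <- Reduce(function(a, b) {
    data.frame(mass = as.vector(outer(a$mass, b$mass, `+`)),
               p = as.vector(outer(a$p, b$p, `*`)))
  }, per_elem)
  d <- d[d$p > 1e-12, ]
  d <- d[order(d$mass), ]
  grp <- cumsum(c(1, diff(d$mass) > merge_da))
  p <- tapply(d$p, grp, sum)
  mz <- tapply(d$p * d$mass, grp, sum) / p
  out <- data.frame(mz = as.numeric(mz), abundance = as.numeric(p / max(p)))
  out[out$abundance >= threshold, ]
}

# Independently coded weighted least squares (matrix algebra, no lm)
oracle_wls <- function(x, y, w) {
  X <- cbind(1, x)
  W <- diag(w)
  beta <- solve(t(X) %*% W %*% X, t(X) %*% W %*% y)
  fitted <- drop(X %*% beta)
  ybar <- sum(w * y) / sum(w)
  r2 <- 1 - sum(w * (y - fitted)^2) / sum(w * (y - ybar)^2)
  list(intercept = beta[1], slope = beta[2], r_squared = r2)
}

# Brute-force MRL: lowest level passing both PIR criteria, from first principles
oracle_mrl <- function(conc_by_level, alpha = 0.01) {
  levels <- sort(as.numeric(names(conc_by_level)))
  for (L in levels) {
    x <- conc_by_level[[as.character(L)]]
    n <- length(x)
    hr <- stats::sd(x) * stats::qt(1 - alpha / 2, n - 1) * sqrt(1 + 1 / n)
    up <- (mean(x) + hr) / L * 100
    lo <- (mean(x) - hr) / L * 100
    if (up <= 150 && lo >= 50) return(L)
  }
  NA_real_
}

# Compact in-code registry: 4 analytes (incl. a zwitterion and a
# decarboxylating ether acid) + 3 internal standards.
mini_registry <- function() {
  df <- data.frame(
    id = c("PFBA", "PFOA", "FTS_6_2", "N_AP_FHxSA",
           "IS_PFBA", "IS_PFOA", "IS_FTS_6_2"),
    name = c("PFBA", "PFOA", "6:2 FTS", "N-AP-FHxSA",
             "13C3-PFBA", "13C8-PFOA", "13C2/D4-6:2 FTS"),
    class = c("carboxylate", "carboxylate", "fluorotelomer_sulfonate",
              "zwitterion", "carboxylate", "carboxylate",
              "fluorotelomer_sulfonate"),
    formula = c("C4HF7O2", "C8HF15O2", "C8H5F13O3S", "C11H13F13N2O2S",
                "C4HF7O2", "C8HF15O2", "C8H5F13O3S"),
    mz = NA_real_,
    species = c("[M-H]-", "[M-H]-", "[M-H]-", "[M+H]+",
                "[M-H]-", "[M-H]-", "[M-H]-"),
    polarity = c("negative", "negative", "negative", "positive",
                 "negative", "negative", "negative"),
    rt_min = c(2.6, 7.6, 8.3, 9.8, 2.6, 7.6, 8.3),
    role = c(rep("analyte", 4), rep("internal_standard", 3)),
    n13C = c(0, 0, 0, 0, 3, 8, 2),
    n2H = c(0, 0, 0, 0, 0, 0, 4),
    surrogate_is = c("IS_PFBA", "IS_PFOA", "IS_FTS_6_2", "IS_FTS_6_2",
                     "", "", ""),
    frag_template = c("168.9888:1.00;68.9952:0.40",
                      "368.9760:1.00;168.9888:0.35",
                      "79.9569:1.00;98.9553:0.45",
                      "58.0651:1.00;104.1070:0.40",
                      "171.9989:1.00", "376.9937:1.00", "81.9637:1.00"),
    early_eluter = c(TRUE, rep(FALSE, 6)),
    stringsAsFactors = FALSE)
  as_compound_registry(df)
}
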