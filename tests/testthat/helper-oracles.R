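# Independent brute-force oracles. These deliberately re-derive each
# quantity from first principles (full sorts, exhaustive pair counting,
# textbook formulas, flat rule lookup) and are used only to check the
# package implementations.

oracle_kw_H <- function(groups) {
  x <- unlist(groups)
  r <- rank(x)
  N <- length(x)
  Rg <- split(r, rep(seq_along(groups), lengths(groups)))
  H <- 12 / (N * (N + 1)) *
    sum(vapply(Rg, function(ri) sum(ri)^2 / length(ri), numeric(1))) -
    3 * (N + 1)
  ties <- table(x)
  H / (1 - sum(ties^3 - ties) / (N^3 - N))
}

oracle_U <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

oracle_U_p <- function(a, b) {
  U <- oracle_U(a, b)
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  ties <- table(c(a, b))
  sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 == 0) return(1)
  z <- (U - n1 * n2 / 2) / sqrt(sigma2)
  2 * min(stats::pnorm(z), stats::pnorm(z, lower.tail = FALSE))
}

# Flat re-implementation of the diagnostic rules: evaluate every
# predicate, then apply the precedence as one lookup chain.
oracle_classify <- function(m, p = analysis_params()) {
  elev <- m$median_irp > p$irp_threshold
  fail100 <- m$pct_failed == 100
  press <- m$pct_pressurization >= p$pressurization_pct
  border <- m$median_irp > p$borderline_irp[1] &
    m$median_irp <= p$borderline_irp[2]
  prem20 <- m$pct_premature >= 20
  no_intact <- m$pct_intact == 0
  he <- m$hyper_count >= 2
  iem <- m$pct_ineffective > 50
  fp <- m$pct_fragmented > 50
  if (elev && fail100 && press) return("T2A")
  if (elev && fail100) return("T1A")
  if (elev && no_intact && prem20) return("T3A")
  if (elev) return("EGJ_OO")
  if (fail100 && border && press) return("ACR")
  if (fail100) return("AC")
  if (prem20 && iem) return("DES_IEM")
  if (prem20) return("DES")
  if (he) return("HE")
  if (iem) return("IEM")
  if (fp) return("FP")
  "NEM"
}

# Random sleeve/gastric toy study for IRP oracle comparisons.
random_sleeve_study <- function() {
  st <- toy_study(0)
  st$pressure[8:9, ] <- matrix(rnorm(2 * 600, 20, 8), 2)
  st$pressure[10:11, ] <- matrix(rnorm(2 * 600, 5, 2), 2)
  st
}
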