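mk_profile <- function(median_irp = 8, pct_failed = 0, pct_weak = 0,
                       pct_premature = 0, pct_fragmented = 0,
                       pct_intact = 100, pct_pressurization = 0,
                       hyper_count = 0) {
  list(median_irp = median_irp, pct_failed = pct_failed,
       pct_weak = pct_weak,
       pct_ineffective = pct_failed + pct_weak,
       pct_premature = pct_premature, pct_fragmented = pct_fragmented,
       pct_intact = pct_intact, pct_pressurization = pct_pressurization,
       hyper_count = hyper_count)
}

test_that("published subgroup median profiles classify to their own labels", {
  # outflow obstruction: elevated IRP with preserved peristalsis
  expect_equal(classify_diagnosis(mk_profile(21.60, pct_intact = 90))$label,
               "EGJ_OO")
  # ineffective motility: normal IRP, 90% ineffective swallows
  expect_equal(classify_diagnosis(mk_profile(8.5, pct_failed = 45,
                                             pct_weak = 45,
                                             pct_intact = 10))$label,
               "IEM")
  # normal motility
  expect_equal(classify_diagnosis(mk_profile(8.9))$label, "NEM")
  # type 2 achalasia: elevated IRP, all failed, pressurization throughout
  expect_equal(classify_diagnosis(mk_profile(26.2, pct_failed = 100,
                                             pct_intact = 0,
                                             pct_pressurization = 100))$label,
               "T2A")
})

test_that("every decision-tree branch is reachable", {
  cases <- list(
    T1A = mk_profile(20, pct_failed = 100, pct_intact = 0),
    T2A = mk_profile(20, pct_failed = 100, pct_intact = 0,
                     pct_pressurization = 20),
    T3A = mk_profile(20, pct_premature = 50, pct_weak = 50,
                     pct_intact = 0),
    EGJ_OO = mk_profile(20, pct_intact = 90),
    AC = mk_profile(5, pct_failed = 100, pct_intact = 0),
    ACR = mk_profile(12, pct_failed = 100, pct_intact = 0,
                     pct_pressurization = 30),
    DES = mk_profile(8, pct_premature = 30, pct_intact = 70),
    HE = mk_profile(8, hyper_count = 2),
    IEM = mk_profile(8, pct_failed = 30, pct_weak = 30, pct_intact = 40),
    FP = mk_profile(8, pct_fragmented = 60, pct_intact = 40),
    DES_IEM = mk_profile(8, pct_premature = 20, pct_weak = 60,
                         pct_intact = 20),
    NEM = mk_profile(8))
  for (lab in names(cases)) {
    dg <- classify_diagnosis(cases[[lab]])
    expect_equal(dg$label, lab)
    expect_gt(length(dg$rule_trace), 0)
  }
})

test_that("type 1 achalasia requires failure without pressurization evidence", {
  expect_equal(classify_diagnosis(mk_profile(20, pct_failed = 100,
                                             pct_intact = 0,
                                             pct_pressurization = 0))$label,
               "T1A")
  expect_equal(classify_diagnosis(mk_profile(20, pct_failed = 100,
                                             pct_intact = 0,
                                             pct_pressurization = 10))$label,
               "T1A")
})

test_that("the 15 mmHg IRP boundary is strict everywhere", {
  expect_equal(irp_category(15.0), "normal")
  expect_equal(irp_category(15.01), "elevated")
  expect_equal(irp_category(11.2), "normal")
  # a profile at exactly 15 goes down the normal-IRP branch
  expect_equal(classify_diagnosis(mk_profile(15, pct_intact = 90))$label,
               "NEM")
  expect_equal(classify_diagnosis(mk_profile(15.01, pct_intact = 90))$label,
               "EGJ_OO")
})

test_that("classifier agrees with a brute-force oracle on 10000 random profiles", {
  set.seed(4242)
  n_bad <- 0
  for (i in 1:10000) {
    # random composition of 10 swallows
    k <- as.vector(stats::rmultinom(1, 10, runif(5)))
    m <- list(median_irp = runif(1, 0, 40),
              pct_failed = 10 * k[1], pct_weak = 10 * k[2],
              pct_ineffective = 10 * (k[1] + k[2]),
              pct_premature = 10 * k[3], pct_fragmented = 10 * k[4],
              pct_intact = 10 * (k[2] + k[5]),
              pct_pressurization = 10 * sample(0:10, 1),
              hyper_count = sample(0:3, 1))
    if (classify_diagnosis(m)$label != oracle_classify(m))
      n_bad <- n_bad + 1
  }
  expect_equal(n_bad, 0)
})

test_that("the decision tree is total over a dense metric grid", {
  labs <- diagnosis_labels()
  seen <- character(0)
  for (irp in c(0, 8, 12, 14, 15, 15.5, 20, 40)) {
    for (fail in seq(0, 100, 20)) for (prem in seq(0, 100, 20)) {
      for (frag in c(0, 40, 60)) for (hyper in 0:2) for (press in c(0, 40)) {
        intact <- max(0, 100 - fail - prem - frag)
        m <- list(median_irp = irp, pct_failed = fail, pct_weak = 0,
                  pct_ineffective = fail, pct_premature = prem,
                  pct_fragmented = frag, pct_intact = intact,
                  pct_pressurization = press,
                  hyper_count = hyper)
        lab <- classify_diagnosis(m)$label
        expect_true(lab %in% labs)
        seen <- union(seen, lab)
      }
    }
  }
  # every rule fires somewhere on the grid
  expect_setequal(setdiff(labs, seen), character(0))
})
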