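# Cohort comparison across thermal-compensation conditions: metric
# summaries, omnibus and pairwise nonparametric tests with a compact
# letter display, diagnosis cross-tabs, and the flip table stratified by
# the reference condition's IRP category.

COHORT_METRICS <- c("uesp", "lesp", "median_irp", "pct_weak", "pct_failed",
                    "pct_ineffective", "pct_pressurization", "pct_premature",
                    "pct_fragmented", "pct_intact", "median_dl",
                    "median_dci")

DIAG_GROUPS <- c(NEM = "NEM", IEM = "IEM", EGJ_OO = "EGJ_OO",
                 T1A = "Achalasia", T2A = "Achalasia", T3A = "Achalasia",
                 AC = "Other", ACR = "Other", DES = "Other", HE = "Other",
                 FP = "Other", DES_IEM = "Other")

#' Collapse a diagnosis label into the flip-table group
#' @param label Diagnosis label(s).
#' @return \code{"NEM"}, \code{"IEM"}, \code{"EGJ_OO"}, \code{"Achalasia"}
#'   or \code{"Other"}.
#' @export
diagnosis_group <- function(label) unname(DIAG_GROUPS[label])

#' Compare a cohort of studies across compensation conditions
#'
#' Runs the full per-study chain (compensate, locate landmarks, metrics,
#' diagnosis) under each condition, then builds the cohort report:
#' per-condition metric summaries gated by the two-test normality rule,
#' Kruskal-Wallis omnibus tests with pairwise Mann-Whitney contrasts and
#' a compact letter display, per-diagnosis chi-square tests with adjusted
#' standardized residuals, and the diagnosis-by-IRP-category flip table
#' stratified by the reference condition. Per-study failures are
#' collected and reported, never silently dropped; the failing study is
#' removed from every condition so all tables share one study set.
#'
#' @param studies List of [pressure_study()] objects, or a manifest
#'   data.frame with a \code{path} column of study-bundle stems.
#' @param conditions Named list of [tc_condition()] objects (default the
#'   five standard ones).
#' @param params An [analysis_params()].
#' @param reference Name of the reference condition for the flip table
#'   (must be in \code{conditions}).
#' @param alpha Significance level for letters and residual flags.
#' @param qc Run [qc_screen()] first and stop if any study is excluded.
#' @return An object of class \code{cohort_comparison}.
#' @export
compare_conditions <- function(studies,
                               conditions = standard_conditions(),
                               params = analysis_params(),
                               reference = "ftc",
                               alpha = 0.05,
                               qc = TRUE) {
  if (is.data.frame(studies)) {
    if (is.null(studies$path))
      stop("compare_conditions: manifest must have a 'path' column",
           call. = FALSE)
    studies <- lapply(studies$path, read_study)
  }
  if (!length(studies))
    stop("compare_conditions: empty cohort", call. = FALSE)
  if (is.null(names(conditions)))
    names(conditions) <- vapply(conditions, `[[`, character(1), "label")
  if (!reference %in% names(conditions))
    stop("compare_conditions: reference condition '", reference,
         "' not among conditions", call. = FALSE)
  ids <- vapply(studies, `[[`, character(1), "study_id")
  names(studies) <- ids

  if (qc) {
    rep_ <- qc_screen_cohort(studies)
    bad <- rep_$study_id[rep_$verdict == "exclude"]
    if (length(bad))
      stop("compare_conditions: studies fail QC screening: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }

  cn <- names(conditions)
  metric_mat <- lapply(cn, function(cond) {
    m <- matrix(NA_real_, nrow = length(ids), ncol = length(COHORT_METRICS),
                dimnames = list(ids, COHORT_METRICS))
    m
  })
  names(metric_mat) <- cn
  diag_mat <- matrix(NA_character_, nrow = length(ids), ncol = length(cn),
                     dimnames = list(ids, cn))
  failures <- data.frame(study_id = character(0), condition = character(0),
                         error = character(0), stringsAsFactors = FALSE)

  for (id in ids) {
    for (cond in cn) {
      res <- tryCatch({
        sm <- analyze_study(studies[[id]], conditions[[cond]], params)
        dg <- classify_diagnosis(sm, params = params)
        list(sm = sm, label = dg$label)
      }, error = function(e) e)
      if (inherits(res, "error")) {
        failures[nrow(failures) + 1L, ] <- list(id, cond,
                                                conditionMessage(res))
      } else {
        metric_mat[[cond]][id, ] <- unlist(res$sm[COHORT_METRICS])
        diag_mat[id, cond] <- res$label
      }
    }
  }
  keep <- ids[stats::complete.cases(diag_mat)]
  if (nrow(failures))
    warning("compare_conditions: ", nrow(failures),
            " per-study failure(s); the affected studies were removed ",
            "from all conditions (see $failures)", call. = FALSE)
  if (!length(keep))
    stop("compare_conditions: no study analyzable under every condition",
         call. = FALSE)
  metric_mat <- lapply(metric_mat, function(m) m[keep, , drop = FALSE])
  diag_mat <- diag_mat[keep, , drop = FALSE]

  # summaries with the normality reporting gate
  summaries <- do.call(rbind, lapply(COHORT_METRICS, function(met) {
    do.call(rbind, lapply(cn, function(cond) {
      x <- metric_mat[[cond]][, met]
      x <- x[is.finite(x)]
      gate <- normality_gate(x, alpha)
      q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(metric = met, condition = cond, n = length(x),
                 median = q[2], q1 = q[1], q3 = q[3],
                 mean = mean(x), sd = stats::sd(x),
                 normal = gate$normal, stringsAsFactors = FALSE)
    }))
  }))

  kw <- do.call(rbind, lapply(COHORT_METRICS, function(met) {
    groups <- lapply(cn, function(cond) {
      x <- metric_mat[[cond]][, met]; x[is.finite(x)]
    })
    if (any(!vapply(groups, length, integer(1))))
      return(data.frame(metric = met, H = NA_real_, df = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    r <- kruskal_wallis(groups)
    data.frame(metric = met, H = r$H, df = r$df, p = r$p,
               stringsAsFactors = FALSE)
  }))

  pairwise <- lapply(COHORT_METRICS, function(met) {
    pm <- matrix(NA_real_, length(cn), length(cn),
                 dimnames = list(cn, cn))
    for (i in seq_along(cn)) for (j in seq_along(cn)) {
      if (i < j) {
        a <- metric_mat[[cn[i]]][, met]; a <- a[is.finite(a)]
        b <- metric_mat[[cn[j]]][, met]; b <- b[is.finite(b)]
        if (length(a) && length(b))
          pm[i, j] <- pm[j, i] <- mann_whitney(a, b)$p
      }
    }
    pm
  })
  names(pairwise) <- COHORT_METRICS

  letters_ <- lapply(COHORT_METRICS, function(met) {
    p_omni <- kw$p[kw$metric == met]
    if (is.finite(p_omni) && p_omni < alpha)
      letter_display(pairwise[[met]], alpha)
    else
      letter_display(matrix(1, length(cn), length(cn),
                            dimnames = list(cn, cn)), alpha)
  })
  names(letters_) <- COHORT_METRICS

  diag_counts <- vapply(cn, function(cond)
    table(factor(diag_mat[, cond], levels = diagnosis_labels())),
    integer(length(diagnosis_labels())))
  rownames(diag_counts) <- diagnosis_labels()
  present <- rowSums(diag_counts) > 0
  chisq_overall <- if (sum(present) >= 2)
    tryCatch(chisq_homogeneity(diag_counts[present, , drop = FALSE]),
             error = function(e) NULL) else NULL
  n_keep <- length(keep)
  per_diag <- do.call(rbind, lapply(diagnosis_labels()[present],
                                    function(d) {
    tab <- rbind(diag_counts[d, ], n_keep - diag_counts[d, ])
    p <- tryCatch(chisq_homogeneity(tab)$p, error = function(e) NA_real_)
    data.frame(diagnosis = d, p = p, stringsAsFactors = FALSE)
  }))

  irp_mat <- vapply(cn, function(cond) metric_mat[[cond]][, "median_irp"],
                    numeric(length(keep)))
  if (length(keep) == 1L)
    irp_mat <- matrix(irp_mat, nrow = 1, dimnames = list(keep, cn))
  cross <- build_flip_table(diag_mat, irp_mat, reference, params)

  structure(list(conditions = cn, study_ids = keep,
                 metrics = metric_mat, diagnoses = diag_mat,
                 summaries = summaries, kw = kw, pairwise = pairwise,
                 letters = letters_, diag_counts = diag_counts,
                 chisq = list(overall = chisq_overall,
                              per_diagnosis = per_diag),
                 cross_tab = cross, failures = failures,
                 reference = reference, alpha = alpha),
            class = "cohort_comparison")
}

#' @export
print.cohort_comparison <- function(x, ...) {
  cat(sprintf("<cohort_comparison> %d studies x %d conditions (%s)\n",
              length(x$study_ids), length(x$conditions),
              paste(x$conditions, collapse = ", ")))
  sig <- x$kw$metric[is.finite(x$kw$p) & x$kw$p < x$alpha]
  cat("  omnibus-significant metrics: ",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n",
      sep = "")
  invisible(x)
}

#' Diagnosis-by-IRP-category flip table
#'
#' Stratifies the cohort by the reference condition's IRP category
#' (normal vs elevated) and counts, per condition, the diagnoses within
#' each stratum, collapsed to the groups NEM, IEM, EGJ-OO, Achalasia and
#' Other. Because elevated-IRP diagnoses (EGJ-OO, achalasia types) cannot
#' occur without elevated IRP and vice versa, off-stratum diagnoses give
#' the per-condition IRP-category flip counts.
#'
#' @param diagnoses Character matrix of labels, studies in rows and
#'   conditions in columns (dimnames required).
#' @param irp Numeric matrix of median IRP, same shape.
#' @param reference Column name of the reference condition.
#' @param params An [analysis_params()].
#' @return An object of class \code{flip_table}: list with \code{tab}
#'   (one row per condition x stratum, one column per diagnosis group),
#'   \code{strata} (reference-category per study), \code{flips}
#'   (per-condition counts of IRP-category changes relative to the
#'   reference, up = normal to elevated, down = elevated to normal) and
#'   \code{stratum_sizes}.
#' @export
build_flip_table <- function(diagnoses, irp, reference = "ftc",
                             params = analysis_params()) {
  stopifnot(is.matrix(diagnoses), is.matrix(irp),
            all(dim(diagnoses) == dim(irp)))
  cn <- colnames(diagnoses)
  if (is.null(cn) || !reference %in% cn)
    stop("build_flip_table: reference condition not among columns",
         call. = FALSE)
  if (!setequal(rownames(diagnoses), rownames(irp)))
    stop("build_flip_table: mismatched study sets", call. = FALSE)
  irp <- irp[rownames(diagnoses), , drop = FALSE]
  strata <- ifelse(irp[, reference] > params$irp_threshold,
                   "irp_elevated", "irp_normal")
  groups <- c("NEM", "IEM", "EGJ_OO", "Achalasia", "Other")
  rows <- list()
  for (cond in cn) for (s in c("irp_normal", "irp_elevated")) {
    in_s <- strata == s
    g <- factor(diagnosis_group(diagnoses[in_s, cond]), levels = groups)
    rows[[paste(cond, s)]] <- data.frame(
      condition = cond, stratum = s,
      as.list(table(g)), stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  cat_mat <- ifelse(irp > params$irp_threshold, "elevated", "normal")
  flips <- do.call(rbind, lapply(cn, function(cond) {
    data.frame(condition = cond,
               up = sum(cat_mat[, reference] == "normal" &
                          cat_mat[, cond] == "elevated"),
               down = sum(cat_mat[, reference] == "elevated" &
                            cat_mat[, cond] == "normal"),
               stringsAsFactors = FALSE)
  }))
  structure(list(tab = tab, strata = strata, flips = flips,
                 stratum_sizes = c(
                   irp_normal = sum(strata == "irp_normal"),
                   irp_elevated = sum(strata == "irp_elevated")),
                 reference = reference),
            class = "flip_table")
}

#' Margins of a flip-table data frame
#'
#' Row sums per condition and stratum plus per-condition totals; used for
#' fixture arithmetic and partition checks (each condition's two stratum
#' sums are invariant and add up to the cohort size).
#'
#' @param tab A flip-table data frame (columns \code{condition},
#'   \code{stratum}, then the five diagnosis groups).
#' @return List with \code{stratum_sums} (condition x stratum matrix) and
#'   \code{totals} (per condition).
#' @export
flip_table_margins <- function(tab) {
  groups <- c("NEM", "IEM", "EGJ_OO", "Achalasia", "Other")
  conds <- unique(tab$condition)
  strata <- unique(tab$stratum)
  m <- matrix(0L, length(conds), length(strata),
              dimnames = list(conds, strata))
  for (i in seq_len(nrow(tab)))
    m[tab$condition[i], tab$stratum[i]] <-
      sum(as.integer(tab[i, groups]))
  list(stratum_sums = m, totals = rowSums(m))
}

#' IRP-category flips implied by a flip-table's diagnoses
#'
#' Diagnoses pin the IRP category: EGJ-OO and the achalasia types require
#' an elevated median IRP, while NEM, IEM and the Other group arise on the
#' normal-IRP branch. A vigorous-IRP diagnosis inside the reference
#' normal stratum therefore implies an upward category flip under that
#' condition, and conversely. These are lower bounds on the true flip
#' counts (metric flips without a diagnosis change are invisible).
#'
#' @param tab A flip-table data frame as in [flip_table_margins()].
#' @return Data frame with \code{condition}, \code{implied_up},
#'   \code{implied_down}.
#' @export
implied_flips <- function(tab) {
  conds <- unique(tab$condition)
  do.call(rbind, lapply(conds, function(cond) {
    lo <- tab[tab$condition == cond & tab$stratum == "irp_normal", ]
    hi <- tab[tab$condition == cond & tab$stratum == "irp_elevated", ]
    data.frame(condition = cond,
               implied_up = as.integer(lo$EGJ_OO + lo$Achalasia),
               implied_down = as.integer(hi$NEM + hi$IEM + hi$Other),
               stringsAsFactors = FALSE)
  }))
}

#' Packaged transcription of the published flip table
#'
#' Reads the verbatim transcription of the published change-in-IRP and
#' final-diagnosis cross-tabulation (counts of diagnoses per compensation
#' condition within the two reference-IRP strata of a 124-study cohort)
#' shipped with the package.
#'
#' @return Data frame in the [build_flip_table()] \code{tab} layout.
#' @export
read_flip_fixture <- function() {
  f <- system.file("extdata", "flip_table_counts.csv",
                   package = "manodrift", mustWork = TRUE)
  as.data.frame(data.table::fread(f))
}
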