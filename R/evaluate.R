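#' Score predictions against true labels
#'
#' Builds the 15 x 15 confusion matrix (rows = true class, columns =
#' predicted class), the overall accuracy `100 * trace / total` and the
#' per-class recall.
#'
#' @param pred,true Equal-length integer class-label vectors.
#' @param classes Full class set (default 1:15).
#' @param subject_id Optional subject identifier carried in the report.
#' @return A `semg_evaluation`: `accuracy` (%), `confusion` (counts),
#'   `per_class_recall` (%, `NA` for classes absent from `true`),
#'   `n`, `subject_id`.
#' @export
score_predictions <- function(pred, true, classes = CLASS_IDS, subject_id = NA_character_) {
  if (length(pred) == 0 || length(true) == 0) stop("cannot score empty label sequences")
  if (length(pred) != length(true)) stop("pred and true must have equal length")
  if (!all(true %in% classes) || !all(pred %in% classes)) {
    stop("labels outside the class set ", min(classes), "-", max(classes))
  }
  confusion <- table(
    true = factor(true, levels = classes),
    predicted = factor(pred, levels = classes)
  )
  confusion <- unclass(confusion)
  total <- sum(confusion)
  row_tot <- rowSums(confusion)
  recall <- ifelse(row_tot > 0, 100 * diag(confusion) / row_tot, NA_real_)
  structure(
    list(
      accuracy = 100 * sum(diag(confusion)) / total,
      confusion = confusion,
      per_class_recall = recall,
      n = total,
      subject_id = subject_id
    ),
    class = "semg_evaluation"
  )
}

#' @export
print.semg_evaluation <- function(x, ...) {
  cat(sprintf(
    "<semg_evaluation> %s: %.2f%% accuracy on %d windows\n",
    x$subject_id, x$accuracy, x$n
  ))
  invisible(x)
}

# Adjacent finger-pinch pairs within one arm position (class ids).
adjacent_pinch_pairs <- function() {
  rbind(c(5, 6), c(6, 7), c(7, 8), c(12, 13), c(13, 14), c(14, 15))
}

#' Fraction of pinch errors landing on the adjacent finger
#'
#' Among misclassified windows whose true class is a finger pinch
#' (classes 5-8 and 12-15), the fraction predicted as the pinch of an
#' adjacent finger in the same arm position (index-middle, middle-ring,
#' ring-little). Returns 0 when no pinch window is misclassified. Under
#' uniform error spreading each misclassified window would land on an
#' adjacent pinch with probability 2/14 or 1/14 (middle classes have two
#' adjacent neighbours, end classes one, out of 14 wrong classes), so a
#' clearly larger observed fraction indicates the middle/ring/little
#' co-contraction confusion structure.
#'
#' @param report A `semg_evaluation` over the full 15-class set, or a
#'   confusion matrix with class-id dimnames.
#' @return Fraction in \[0, 1\].
#' @export
adjacent_pinch_confusion <- function(report) {
  confusion <- if (inherits(report, "semg_evaluation")) report$confusion else report
  ids <- as.integer(rownames(confusion))
  stopifnot(all(PINCH_CLASSES %in% ids))
  pinch_rows <- match(PINCH_CLASSES, ids)
  errors <- confusion[pinch_rows, , drop = FALSE]
  diag_idx <- cbind(seq_along(pinch_rows), match(PINCH_CLASSES, ids))
  errors[diag_idx] <- 0
  total_errors <- sum(errors)
  if (total_errors == 0) {
    return(0)
  }
  pairs <- adjacent_pinch_pairs()
  adj <- 0
  for (k in seq_len(nrow(pairs))) {
    a <- pairs[k, 1]
    b <- pairs[k, 2]
    adj <- adj + confusion[match(a, ids), match(b, ids)] +
      confusion[match(b, ids), match(a, ids)]
  }
  adj / total_errors
}

#' Cohort-level summary of accuracy and strength
#'
#' Summarizes per-subject classification accuracy and strength maxima by
#' group: group means, the relative percent decrease in mean force and
#' torque from the young to the senior group
#' (`100 * (young - senior) / young`), the accuracy decrease in
#' percentage points (`young - senior`), and within each group the
#' least-squares slope and Pearson correlation of accuracy against
#' maximum force and maximum torque (reported as `NA` when a group has
#' fewer than 3 subjects).
#'
#' @param subjects Data.frame with columns `subject`, `group`
#'   (`"senior"`/`"young"`), `accuracy_pct`, `max_force_N`,
#'   `max_torque_Nm`.
#' @return A `semg_cohort_summary`: the `subjects` table, a `groups`
#'   data.frame of means and fits, and the between-group contrasts.
#' @export
cohort_summary <- function(subjects) {
  required <- c("subject", "group", "accuracy_pct", "max_force_N", "max_torque_Nm")
  missing <- setdiff(required, names(subjects))
  if (length(missing)) {
    stop("subject table is missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(subjects) < 1) stop("subject table is empty")
  groups <- unique(subjects$group)
  fit_stats <- function(acc, x) {
    if (length(acc) < 3 || stats::sd(x) == 0 || stats::sd(acc) == 0) {
      return(c(slope = NA_real_, cor = NA_real_))
    }
    fit <- stats::lm(acc ~ x)
    c(slope = unname(stats::coef(fit)[2]), cor = stats::cor(acc, x))
  }
  gs <- do.call(rbind, lapply(groups, function(g) {
    sub <- subjects[subjects$group == g, , drop = FALSE]
    ff <- fit_stats(sub$accuracy_pct, sub$max_force_N)
    ft <- fit_stats(sub$accuracy_pct, sub$max_torque_Nm)
    data.frame(
      group = g,
      n = nrow(sub),
      mean_accuracy_pct = mean(sub$accuracy_pct),
      mean_force_N = mean(sub$max_force_N),
      mean_torque_Nm = mean(sub$max_torque_Nm),
      force_slope = ff["slope"], force_cor = ff["cor"],
      torque_slope = ft["slope"], torque_cor = ft["cor"],
      row.names = NULL
    )
  }))
  contrasts <- NULL
  if (all(c("senior", "young") %in% groups)) {
    sen <- gs[gs$group == "senior", ]
    yng <- gs[gs$group == "young", ]
    contrasts <- list(
      force_decrease_pct = 100 * (yng$mean_force_N - sen$mean_force_N) / yng$mean_force_N,
      torque_decrease_pct = 100 * (yng$mean_torque_Nm - sen$mean_torque_Nm) / yng$mean_torque_Nm,
      accuracy_decrease_points = yng$mean_accuracy_pct - sen$mean_accuracy_pct
    )
  }
  structure(
    list(subjects = subjects, groups = gs, contrasts = contrasts),
    class = "semg_cohort_summary"
  )
}

#' @export
print.semg_cohort_summary <- function(x, ...) {
  cat("<semg_cohort_summary>\n")
  print(x$groups, digits = 4)
  if (!is.null(x$contrasts)) {
    cat(sprintf(
      "young -> senior: force -%.1f%%, torque %+.1f%%, accuracy -%.2f points\n",
      x$contrasts$force_decrease_pct,
      -x$contrasts$torque_decrease_pct,
      x$contrasts$accuracy_decrease_points
    ))
  }
  invisible(x)
}

#' Reference cohort accuracy and strength tables
#'
#' Loads the per-subject reference measurements shipped with the package
#' (`inst/extdata/reference_cohort_seniors.csv` and
#' `reference_cohort_young.csv`): classification accuracy, maximum grip
#' force and maximum wrist torque for a 12-senior and a 7-young cohort,
#' transcribed from the motivating study's published per-subject results.
#'
#' @return Data.frame in the format [cohort_summary()] expects.
#' @export
reference_cohort_table <- function() {
  paths <- c(
    system.file("extdata", "reference_cohort_seniors.csv", package = "semgpipe"),
    system.file("extdata", "reference_cohort_young.csv", package = "semgpipe")
  )
  do.call(rbind, lapply(paths, utils::read.csv, stringsAsFactors = FALSE))
}
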