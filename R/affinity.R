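# Affinity tables: Ki/pKi bookkeeping and external-validation statistics.

#' Convert an inhibition constant Ki to pKi
#'
#' pKi is the negative decadic logarithm of Ki expressed in molar units.
#'
#' @param ki Positive numeric vector of inhibition constants.
#' @param unit Unit of `ki`: `"nM"` (default, divided by 1e9 first) or `"M"`.
#' @return Numeric vector of pKi values.
#' @examples
#' ki_to_pki(3617)        # 5.442
#' ki_to_pki(1e-9, "M")   # 9
#' @export
ki_to_pki <- function(ki, unit = c("nM", "M")) {
  unit <- match.arg(unit)
  if (!is.numeric(ki) || any(!is.finite(ki)) || any(ki <= 0))
    stop("Ki must be positive and finite")
  ki_molar <- if (unit == "nM") ki * 1e-9 else ki
  -log10(ki_molar)
}

#' Construct an affinity table
#'
#' An affinity table holds one receptor's compound records: Ki (nM), actual
#' pKi, optionally a model-predicted pKi and the residual (actual minus
#' predicted), and a train/test split flag.
#'
#' @param df Data frame with columns `receptor`, `molecule_id`, `ki_nM`,
#'   `pki`, `predicted_pki`, `residual`, `split`.
#' @param validate Check internal consistency (pKi vs Ki, residual vs
#'   prediction, unique ids)? Default `TRUE`.
#' @param pki_tol Tolerance for the pKi/Ki consistency check, reflecting the
#'   rounding of printed tables.
#' @return The data frame with class `affinity_table`.
#' @export
affinity_table <- function(df, validate = TRUE, pki_tol = 0.005) {
  needed <- c("receptor", "molecule_id", "ki_nM", "pki",
              "predicted_pki", "residual", "split")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols))
    stop("affinity table lacks columns: ", paste(missing_cols, collapse = ", "))
  if (!all(df$split %in% c("train", "test")))
    stop("split must be 'train' or 'test'")
  if (anyDuplicated(df$molecule_id))
    stop("duplicate molecule_id within an affinity table")
  if (length(unique(df$receptor)) != 1L)
    stop("an affinity table holds a single receptor")
  if (any(df$ki_nM <= 0)) stop("Ki values must be positive")
  if (validate) {
    bad <- check_affinity_consistency(df, pki_tol = pki_tol)
    if (nrow(bad))
      stop("inconsistent rows (molecule_id): ",
           paste(bad$molecule_id, collapse = ", "))
  }
  class(df) <- c("affinity_table", "data.frame")
  df
}

# Rows violating the pKi- or residual-consistency invariants. Printed
# tables round Ki to the shown precision while pKi was computed from the
# unrounded value (e.g. a pKi of 9.187 printed next to Ki 0.7 nM implies
# Ki 0.65 before rounding), so the allowed pKi deviation is the half-ulp
# of the printed Ki propagated to the log scale, floored at `pki_tol` for
# the pKi column's own rounding.
check_affinity_consistency <- function(df, pki_tol = 0.005) {
  half_ulp <- printed_half_ulp(df$ki_nM)
  tol <- pmax(pki_tol, log10(df$ki_nM / pmax(df$ki_nM - half_ulp, 1e-12)))
  pki_dev <- abs(df$pki - ki_to_pki(df$ki_nM))
  res_dev <- ifelse(is.na(df$predicted_pki) | is.na(df$residual), 0,
                    abs(df$residual - (df$pki - df$predicted_pki)))
  df[pki_dev > tol + 1e-9 | res_dev > pki_tol + 1e-9, , drop = FALSE]
}

# Half a unit in the last printed decimal place of each value (values are
# assumed printed with up to 4 decimals).
printed_half_ulp <- function(x) {
  dec <- vapply(x, function(v) {
    for (d in 0:4) if (abs(v * 10^d - round(v * 10^d)) < 1e-9) return(d)
    4L
  }, integer(1))
  10^(-dec) / 2
}

#' Load a packaged receptor affinity fixture
#'
#' Returns the packaged transcription of a published cannabinoid
#' aminoalkylindole binding data set: 49 CB1 records (36 train / 13 test) or
#' 80 CB2 records (60 train / 20 test), with actual and model-predicted pKi.
#'
#' @param receptor `"CB1"` or `"CB2"`.
#' @return An [affinity_table].
#' @examples
#' tab <- load_affinity_table("CB1")
#' table(tab$split)
#' @export
load_affinity_table <- function(receptor = c("CB1", "CB2")) {
  receptor <- match.arg(receptor)
  file <- extdata_path(paste0("affinity_", tolower(receptor), ".csv"))
  df <- read.csv(file, stringsAsFactors = FALSE)
  tab <- affinity_table(df)
  counts <- table(tab$split)
  expected <- if (receptor == "CB1") c(test = 13L, train = 36L)
              else c(test = 20L, train = 60L)
  if (!identical(as.integer(counts[names(expected)]), unname(expected)))
    stop("corrupt fixture: unexpected train/test counts for ", receptor)
  tab
}

#' Residuals (actual minus predicted pKi)
#'
#' @param table An [affinity_table].
#' @param subset `"all"`, `"train"` or `"test"`.
#' @return Data frame with columns `molecule_id` and `residual`
#'   (recomputed as `pki - predicted_pki`), input order preserved.
#' @export
affinity_residuals <- function(table, subset = c("all", "train", "test")) {
  subset <- match.arg(subset)
  sel <- if (subset == "all") rep(TRUE, nrow(table)) else table$split == subset
  rows <- table[sel, , drop = FALSE]
  miss <- rows$molecule_id[is.na(rows$predicted_pki)]
  if (length(miss))
    stop("no predicted pKi for molecule_id: ", paste(miss, collapse = ", "))
  data.frame(molecule_id = rows$molecule_id,
             residual = rows$pki - rows$predicted_pki)
}

#' External-validation statistics (PRESS, SD, predictive r-squared)
#'
#' PRESS is the sum of squared deviations between predicted and actual
#' activity over the test set; SD is the sum of squared deviations between
#' the test-set activities and the mean activity of the training set; the
#' predictive r-squared is (SD - PRESS) / SD.
#'
#' @param table An [affinity_table] with at least one train record and at
#'   least one test record carrying a prediction.
#' @return Object of class `predictive_stats`: a list with `press`, `sd`,
#'   `r2_pred`, `train_mean`, `n_test`.
#' @examples
#' predictive_stats(load_affinity_table("CB1"))
#' @export
predictive_stats <- function(table) {
  train <- table[table$split == "train", , drop = FALSE]
  test <- table[table$split == "test", , drop = FALSE]
  if (nrow(train) == 0L || nrow(test) == 0L)
    stop("need at least one train and one test record")
  if (anyNA(test$predicted_pki))
    stop("test records lack predictions: ",
         paste(test$molecule_id[is.na(test$predicted_pki)], collapse = ", "))
  press <- sum((test$pki - test$predicted_pki)^2)
  train_mean <- mean(train$pki)
  sd_sum <- sum((test$pki - train_mean)^2)
  r2_pred <- if (sd_sum > 0) (sd_sum - press) / sd_sum else NA_real_
  out <- list(press = press, sd = sd_sum, r2_pred = r2_pred,
              train_mean = train_mean, n_test = nrow(test))
  if (sd_sum == 0)
    warning("SD is zero: predictive r-squared is undefined (NA)")
  class(out) <- "predictive_stats"
  out
}

#' @export
print.predictive_stats <- function(x, ...) {
  cat(sprintf("External validation over %d test molecules\n", x$n_test))
  cat(sprintf("  PRESS   %8.3f\n  SD      %8.3f\n  r2_pred %8.3f\n",
              x$press, x$sd, x$r2_pred))
  invisible(x)
}

#' Write an affinity table in the packaged CSV schema
#'
#' @param table An [affinity_table].
#' @param path Output file path.
#' @export
write_affinity_table <- function(table, path) {
  write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
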