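# Time-domain features of the wavelet sub-signals and the fused
# closure + EEG feature table.
#
# Per subband D1..D5, A5: MAV, SD, RMS (18 values) plus the Shannon
# wavelet-energy entropy of D1 only — 19 features per epoch. Column names
# follow the conventional A..F / 1..4 layout: A = D1 ... E = D5, F = A5;
# within a letter, 1 = MAV, 2 = SD, 3 = RMS, and A4 = SE(D1).

#' Mean absolute value
#' @param x numeric coefficient vector.
#' @export
mav <- function(x) {
  if (!length(x)) stop("empty vector")
  mean(abs(x))
}

#' Root mean square
#' @param x numeric coefficient vector.
#' @export
rms <- function(x) {
  if (!length(x)) stop("empty vector")
  sqrt(mean(x^2))
}

#' Shannon wavelet-energy entropy (bits)
#'
#' Entropy of the normalized energy distribution p_i = x_i^2 / sum(x^2),
#' with 0 log 0 taken as 0. Scale-invariant; bounded by log2(length(x)).
#' An all-zero vector is degenerate and yields 0 with a warning.
#'
#' @param x numeric coefficient vector.
#' @export
shannon_entropy <- function(x) {
  if (!length(x)) stop("empty vector")
  e <- x^2
  tot <- sum(e)
  if (tot <= 0) {
    warning("all-zero vector: entropy set to 0")
    return(0)
  }
  p <- e / tot
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Names of the 19 EEG features, in table order
#' @export
EEG_FEATURE_NAMES <- c(
  "A1", "A2", "A3", "A4",
  "B1", "B2", "B3", "C1", "C2", "C3",
  "D1", "D2", "D3", "E1", "E2", "E3",
  "F1", "F2", "F3")

#' Extract the 19-feature vector of one epoch
#'
#' Decomposes the epoch (five-level db5) and computes MAV, SD and RMS for
#' each of the six sub-signals plus the Shannon entropy of D1.
#'
#' @param epoch an [eeg_epoch()] or numeric vector.
#' @return named numeric vector of length 19 (names [EEG_FEATURE_NAMES]).
#' @export
extract_features <- function(epoch) {
  dec <- dwt_decompose(epoch)
  subbands <- c(dec$details, list(A5 = dec$approximation))
  out <- numeric(0)
  for (i in seq_along(subbands)) {
    coefs <- subbands[[i]]
    triple <- c(mav(coefs), stats::sd(coefs), rms(coefs))
    if (i == 1L) {
      se <- if (all(coefs == 0)) { warning("zero D1 subband"); 0 }
            else shannon_entropy(coefs)
      out <- c(out, triple, se)
    } else {
      out <- c(out, triple)
    }
  }
  stats::setNames(out, EEG_FEATURE_NAMES)
}

#' Fuse one sample's closure value and per-channel features into 3 rows
#'
#' The eyelid-closure estimate of the sample (from O2) is replicated to
#' the three frontal-channel rows, so each row is a 20-value input
#' `[ecd, 19 features]` plus the label.
#'
#' @param sample_id sample identifier.
#' @param ecd normalized eECD in \[0, 1\].
#' @param channel_features named list `FP1`, `FP2`, `FZ` of length-19
#'   feature vectors.
#' @param label fatigue label (1 = alert, 2 = middle, 3 = fatigue).
#' @return data frame of 3 rows: `sample_id`, `channel`, `ecd`, the 19
#'   feature columns, `label`.
#' @export
fuse <- function(sample_id, ecd, channel_features, label) {
  need <- c("FP1", "FP2", "FZ")
  missing <- setdiff(need, names(channel_features))
  if (length(missing)) stop("missing channel features: ",
                            paste(missing, collapse = ", "))
  rows <- lapply(need, function(ch) {
    f <- channel_features[[ch]]
    if (length(f) != 19L) stop("feature vector for ", ch, " must have length 19")
    df <- data.frame(sample_id = sample_id, channel = ch, ecd = ecd,
                     stringsAsFactors = FALSE)
    df[EEG_FEATURE_NAMES] <- as.list(unname(f))
    df$label <- label
    df
  })
  do.call(rbind, rows)
}

#' Fit per-feature standardization statistics on training rows
#'
#' @param table feature table (rows from [fuse()]).
#' @param columns columns to standardize (default the 19 EEG features; the
#'   eECD column is already on \[0, 1\]).
#' @return object of class `feature_scaling` (per-column mean and sd).
#' @export
fit_feature_scaling <- function(table, columns = EEG_FEATURE_NAMES) {
  mu <- vapply(columns, function(cn) mean(table[[cn]]), numeric(1))
  sdev <- vapply(columns, function(cn) stats::sd(table[[cn]]), numeric(1))
  structure(list(columns = columns, mean = mu, sd = sdev),
            class = "feature_scaling")
}

#' Standardize feature columns with training-split statistics
#'
#' Z-scores each feature column using statistics fit on the training rows
#' only ([fit_feature_scaling()]), so cross-validation never leaks test
#' information. A zero-variance column is left unscaled with a warning.
#'
#' @param table feature table.
#' @param scaling a `feature_scaling` fit on the training split.
#' @return the table with standardized feature columns.
#' @export
standardize_features <- function(table, scaling) {
  stopifnot(inherits(scaling, "feature_scaling"))
  for (i in seq_along(scaling$columns)) {
    cn <- scaling$columns[i]
    if (scaling$sd[i] <= 0 || !is.finite(scaling$sd[i])) {
      warning("zero-variance feature column left unscaled: ", cn)
      next
    }
    table[[cn]] <- (table[[cn]] - scaling$mean[i]) / scaling$sd[i]
  }
  table
}

#' Write a feature table as CSV
#' @param table feature table.
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
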