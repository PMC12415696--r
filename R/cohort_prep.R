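# Leakage-free data preparation: per-case tile capping at the cohort median,
# patient-level stratified splitting, and class balancing. All three
# operations act on a tile-level manifest data frame with at least
# `tile_id, patient_id, label` columns, and are deterministic given a seed.

# lower-median convention: an integer tile count is required, so for an even
# number of cases the lower of the two middle values is used
lower_median <- function(x) {
  s <- sort(x)
  s[ceiling(length(s) / 2)]
}

#' Cap per-case tile counts at the cohort median
#'
#' The median is computed over the per-case tile counts of the input (classes
#' pooled); cases above the median are randomly subsampled without
#' replacement to exactly the median, others are untouched.
#'
#' @param manifest Tile-level data frame with `tile_id` and `patient_id`.
#' @param seed Integer seed for the subsampling.
#' @return The capped manifest (a subset of the input rows), with the applied
#'   median in attribute `"cap"`.
#' @export
cap_tiles <- function(manifest, seed = 1L) {
  if (is.null(manifest) || !NROW(manifest)) abort("empty cohort: no tiles to cap")
  counts <- table(manifest$patient_id)
  med <- lower_median(as.integer(counts))
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(manifest)), manifest$patient_id), function(idx) {
      if (length(idx) > med) sort(sample(idx, med)) else idx
    }), use.names = FALSE)
  })
  out <- manifest[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "cap") <- med
  out
}

# largest-remainder apportionment of n into parts proportional to `ratios`;
# remainder ties are broken in ratio order (train before val before test).
# When n allows (one patient per set), empty sets are topped up from the
# largest set so that every set is populated for n >= length(ratios).
apportion <- function(n, ratios) {
  exact <- n * ratios
  base <- floor(exact)
  rem <- exact - base
  left <- n - sum(base)
  if (left > 0) {
    ord <- order(-rem, seq_along(ratios))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  if (n >= length(ratios)) {
    for (j in rev(seq_along(base))) {
      if (base[j] == 0L) {
        donor <- which.max(base)
        base[donor] <- base[donor] - 1
        base[j] <- 1
      }
    }
  }
  as.integer(base)
}

#' Stratified patient-level split
#'
#' Patients are randomly assigned to train/validation/test within class
#' strata; per-class counts follow largest-remainder apportionment of the
#' ratios. Tiles inherit their patient's set, so no patient's tiles appear in
#' more than one set.
#'
#' @param manifest Tile-level data frame with `patient_id` and `label`.
#' @param ratios Length-3 fractions `(train, val, test)` summing to 1.
#' @param seed Integer seed.
#' @return A `split_assignment`: data frame `patient_id, class, set` with the
#'   ratios and seed as attributes.
#' @export
split_patients <- function(manifest, ratios = c(0.6, 0.3, 0.1), seed = 1L) {
  if (length(ratios) != 3L || abs(sum(ratios) - 1) > 1e-8)
    abort("ratios must be three fractions summing to 1")
  pts <- unique(manifest[, c("patient_id", "label")])
  sets <- c("train", "val", "test")
  pieces <- with_seed(seed, {
    lapply(split(pts$patient_id, pts$label), function(ids) {
      if (length(ids) == 0L) abort("a class has 0 patients")
      ids <- sample(ids)
      n_k <- apportion(length(ids), ratios)
      data.frame(patient_id = ids, set = rep(sets, n_k), stringsAsFactors = FALSE)
    })
  })
  if (length(pieces) < 2L) abort("a class has 0 patients")
  out <- do.call(rbind, pieces)
  out$class <- pts$label[match(out$patient_id, pts$patient_id)]
  out <- out[order(out$patient_id), c("patient_id", "class", "set")]
  rownames(out) <- NULL
  structure(out, ratios = ratios, seed = as.integer(seed),
            class = c("split_assignment", "data.frame"))
}

#' Attach split assignments to a tile manifest
#'
#' @param manifest Tile-level data frame with `patient_id`.
#' @param split A `split_assignment` from [split_patients()].
#' @return The manifest with a `set` column.
#' @export
assign_tiles <- function(manifest, split) {
  manifest$set <- split$set[match(manifest$patient_id, split$patient_id)]
  if (anyNA(manifest$set)) abort("manifest contains patients absent from the split")
  manifest
}

#' Write / read a split assignment CSV
#'
#' Columns `patient_id, class, set`; reproducible from the cohort manifest
#' and seed.
#'
#' @param split A `split_assignment`.
#' @param path Output CSV path.
#' @return `write_split()`: `path` invisibly; `read_split()`: the assignment.
#' @export
write_split <- function(split, path) {
  write.csv(as.data.frame(split), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_split
#' @export
read_split <- function(path) {
  out <- read.csv(path, stringsAsFactors = FALSE)
  structure(out, class = c("split_assignment", "data.frame"))
}

#' Balance class counts by random removal
#'
#' Randomly removes tiles from the class with more tiles until both classes
#' have the smaller class's count. Intended for the training and validation
#' sets; the test set is left imbalanced to mimic deployment conditions.
#'
#' @param manifest Tile-level data frame with `tile_id` and `label`; both
#'   classes must be present.
#' @param seed Integer seed.
#' @return The balanced manifest (a subset of the input rows).
#' @export
balance_classes <- function(manifest, seed = 1L) {
  n0 <- sum(manifest$label == 0L)
  n1 <- sum(manifest$label == 1L)
  if (n0 == 0L || n1 == 0L) abort("both classes must be present to balance")
  m <- min(n0, n1)
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(nrow(manifest)), manifest$label), function(idx) {
      if (length(idx) > m) sort(sample(idx, m)) else idx
    }), use.names = FALSE)
  })
  out <- manifest[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
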