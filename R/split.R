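#' Rank-ordered calibration/validation split
#'
#' Partitions samples into calibration and validation sets the way NIRS
#' calibration sets are conventionally built: samples are sorted in ascending
#' order of the chosen trait (ties broken by sample id), and the validation
#' samples are taken at evenly spaced ranks strictly inside the sorted order.
#' The global minimum and maximum of the trait therefore always land in the
#' calibration set, so calibration spans the full trait range, while both
#' sets sample the whole distribution evenly. The split is deterministic and
#' invariant to the row order of the input.
#'
#' With 139 samples and `n_validation = 40` this yields the conventional
#' 99/40 (roughly 2:1) partition.
#'
#' @param reference a reference tibble.
#' @param trait name of the trait column to sort on.
#' @param n_validation number of validation samples (between 1 and n - 2).
#' @return an object of class `split_result`: tibble with columns
#'   `sample_id`, `set` (`"cal"`/`"val"`), plus attributes `trait` and
#'   `ratio`.
#' @examples
#' ref <- simulate_reference(139, seed = 1)
#' sp <- rank_ordered_split(ref, "protein", 40)
#' table(sp$set)
#' @export
rank_ordered_split <- function(reference, trait, n_validation) {
  reference <- validate_reference(reference)
  if (!trait %in% names(reference)) {
    abort(sprintf("Trait '%s' not found in the reference table.", trait))
  }
  n <- nrow(reference)
  if (n_validation < 1 || n_validation > n - 2) {
    abort(sprintf("`n_validation` must be between 1 and n - 2 = %d.", n - 2))
  }
  ord <- order(reference[[trait]], reference$sample_id)
  ids <- reference$sample_id[ord]
  # evenly spaced interior ranks 2..(n-1); spacing >= 1 keeps them distinct
  val_ranks <- 1L + round(seq(1, n - 2, length.out = n_validation))
  set <- rep("cal", n)
  set[val_ranks] <- "val"
  out <- tibble::tibble(sample_id = ids, rank = seq_len(n),
                        value = reference[[trait]][ord], set = set)
  structure(out, trait = trait,
            ratio = sprintf("%d:%d", n - n_validation, n_validation),
            class = c("split_result", class(out)))
}

#' @rdname rank_ordered_split
#' @param split a `split_result`.
#' @param table a spectra or reference tibble to subset by the split.
#' @param set which side to keep.
#' @export
split_subset <- function(split, table, set = c("cal", "val")) {
  set <- match.arg(set)
  ids <- split$sample_id[split$set == set]
  idx <- match(ids, table$sample_id)
  if (anyNA(idx)) {
    abort(paste0("Sample id(s) in the split but not in the table: ",
                 paste(utils::head(ids[is.na(idx)], 5), collapse = ", ")))
  }
  table[idx, , drop = FALSE]
}
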