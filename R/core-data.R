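#' Read a paired-sample manifest
#'
#' A manifest is a UTF-8 CSV with header columns `sample_id`,
#' `image_path`, `audio_path`, `label` linking each thermal image to its
#' simultaneously recorded audio clip. Labels may be written as
#' `estrus`/`non_estrus` or `1`/`0`; estrus is the positive class and is
#' stored as integer 1. Referenced files are *not* opened here —
#' unreadable paths surface later, when a pipeline stage reads them.
#'
#' @param path path to the manifest CSV.
#' @return A tibble with columns `sample_id` (character), `image_path`,
#'   `audio_path` (character) and `label` (integer 0/1), one row per
#'   pair, in file order.
#' @export
read_manifest <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                        progress = FALSE)
  req <- c("sample_id", "image_path", "audio_path", "label")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    rlang::abort(paste0("manifest is missing column(s): ",
                        paste(missing, collapse = ", ")))
  }
  lab <- dplyr::case_match(tolower(df$label),
                           c("estrus", "1") ~ 1L,
                           c("non_estrus", "non-estrus", "0") ~ 0L,
                           .default = NA_integer_)
  if (anyNA(lab) && nrow(df) > 0) {
    bad <- unique(df$label[is.na(lab)])
    rlang::abort(paste0("unrecognized label value(s): ",
                        paste(bad, collapse = ", ")))
  }
  if (anyDuplicated(df$sample_id)) {
    rlang::abort("duplicate sample_id in manifest")
  }
  tibble::tibble(
    sample_id = df$sample_id,
    image_path = df$image_path,
    audio_path = df$audio_path,
    label = lab
  )
}

#' Write a paired-sample manifest
#'
#' @param pairs a tibble as returned by [read_manifest()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(pairs, path) {
  out <- dplyr::mutate(tibble::as_tibble(pairs),
                       label = ifelse(.data$label == 1L, "estrus", "non_estrus"))
  readr::write_csv(out[, c("sample_id", "image_path", "audio_path", "label")],
                   path, progress = FALSE)
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Partitions paired samples into train, validation and test sets in the
#' given proportions (default 6:2:2), stratified by label so each split
#' preserves class balance to within one sample per class. Within each
#' class the per-split sizes are the floored proportions, with remainder
#' samples assigned to train first, then validation. The split is a
#' deterministic function of `seed`.
#'
#' @param pairs tibble of pairs (columns `sample_id`, `label`, ...).
#' @param ratios numeric length-3 vector of proportions summing to 1.
#' @param seed integer seed controlling the shuffle.
#' @return The input tibble with a `split` factor column
#'   (`train`/`val`/`test`) appended; attribute `ratios` and `seed`
#'   record the call.
#' @examples
#' pairs <- tibble::tibble(sample_id = sprintf("s%02d", 1:10),
#'                         image_path = "x.png", audio_path = "x.wav",
#'                         label = rep(0:1, each = 5))
#' table(split_dataset(pairs, seed = 1)$split)
#' @export
split_dataset <- function(pairs, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  pairs <- tibble::as_tibble(pairs)
  stopifnot(length(ratios) == 3, all(ratios >= 0))
  if (abs(sum(ratios) - 1) > 1e-9) rlang::abort("ratios must sum to 1")
  if (nrow(pairs) < 5) rlang::abort("need at least 5 pairs to split")
  n_splits <- sum(ratios > 0)
  counts <- table(pairs$label)
  if (any(counts < n_splits)) {
    rlang::abort("each class needs at least as many samples as nonempty splits")
  }
  assign_class <- function(n) {
    sizes <- floor(ratios * n)
    rem <- n - sum(sizes)
    # leftover samples go to train first, then val
    if (rem > 0) {
      add <- rep(1:2, length.out = rem)
      for (a in add) sizes[a] <- sizes[a] + 1
    }
    rep(c("train", "val", "test"), times = sizes)
  }
  out <- withr::with_seed(as.integer(seed), {
    split_col <- character(nrow(pairs))
    for (lb in sort(unique(pairs$label))) {
      idx <- which(pairs$label == lb)
      split_col[sample(idx)] <- assign_class(length(idx))
    }
    split_col
  })
  res <- dplyr::mutate(pairs,
                       split = factor(out, levels = c("train", "val", "test")))
  attr(res, "ratios") <- ratios
  attr(res, "seed") <- as.integer(seed)
  res
}

#' Write a split to disk as three manifests plus a JSON sidecar
#'
#' Writes `train.csv`, `val.csv`, `test.csv` in manifest format, and
#' `split.json` recording the seed and ratios used, to `dir`.
#'
#' @param split a tibble from [split_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_split <- function(split, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in c("train", "val", "test")) {
    write_manifest(split[split$split == s, , drop = FALSE],
                   file.path(dir, paste0(s, ".csv")))
  }
  side <- list(seed = attr(split, "seed"), ratios = attr(split, "ratios"),
               sizes = as.list(table(split$split)))
  jsonlite::write_json(side, file.path(dir, "split.json"), auto_unbox = TRUE)
  invisible(dir)
}
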