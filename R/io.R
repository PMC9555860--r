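# TSV / NIfTI / JSON writers. Every writer emits a JSON sidecar carrying the
# analysis seed and a content hash so outputs are traceable to their config.

fmt_num <- function(x) {
  ifelse(x == round(x) & abs(x) < 2^31, format(x, scientific = FALSE),
         sprintf("%.17g", x))
}

write_sidecar <- function(path, meta) {
  side <- paste0(path, ".json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(side)
}

#' Write / read a per-parcel map as TSV
#'
#' Columns `parcel_id` and `value`; numeric values are written with full
#' double precision so a read-back round-trips to 1e-12. A JSON sidecar
#' (`<path>.json`) records the seed and any extra metadata.
#'
#' @param map tibble with `parcel` (or `parcel_id`) and `value` columns, or
#'   a plain numeric vector.
#' @param path output TSV path.
#' @param meta named list written to the sidecar (e.g. `seed`, config hash).
#' @return `path`, invisibly.
#' @export
write_parcel_map <- function(map, path, meta = list()) {
  if (is.data.frame(map)) {
    ids <- map[["parcel_id"]] %||% map[["parcel"]]
    vals <- map[["value"]] %||% map[["difference"]] %||% map[["z"]]
  } else {
    ids <- seq_along(map)
    vals <- as.numeric(map)
  }
  lines <- c(
    "parcel_id\tvalue",
    paste(ids, fmt_num(vals), sep = "\t")
  )
  writeLines(lines, path)
  write_sidecar(path, c(meta, list(hash = hash(list(ids, vals)))))
  invisible(path)
}

#' @rdname write_parcel_map
#' @export
read_parcel_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t")
  tibble(parcel_id = df$parcel_id, value = as.numeric(df$value))
}

#' Write / read a connectivity matrix as TSV
#'
#' Square TSV with a header row of parcel ids; metadata (condition,
#' participant, number of valid trial pairs) goes to the JSON sidecar.
#'
#' @param ic an `ic_matrix` (or plain square matrix).
#' @param path output TSV path.
#' @param meta extra sidecar entries.
#' @return `path`, invisibly.
#' @export
write_ic_matrix <- function(ic, path, meta = list()) {
  m <- unclass(ic)
  ids <- attr(ic, "parcel_ids") %||% seq_len(ncol(m))
  header <- paste(ids, collapse = "\t")
  rows <- apply(m, 1, function(r) paste(fmt_num(r), collapse = "\t"))
  writeLines(c(header, rows), path)
  write_sidecar(path, c(meta, list(
    condition = attr(ic, "condition"),
    participant_id = attr(ic, "participant_id"),
    n_valid_pairs = attr(ic, "n_valid_pairs"),
    hash = hash(m)
  )))
  invisible(path)
}

#' @rdname write_ic_matrix
#' @export
read_ic_matrix <- function(path) {
  lines <- readLines(path)
  ids <- as.integer(strsplit(lines[1], "\t")[[1]])
  m <- do.call(rbind, lapply(lines[-1], function(l) {
    as.numeric(strsplit(l, "\t")[[1]])
  }))
  side <- paste0(path, ".json")
  meta <- if (file.exists(side)) jsonlite::read_json(side) else list()
  structure(
    m,
    condition = meta$condition %||% "all",
    participant_id = meta$participant_id %||% NA_character_,
    n_valid_pairs = meta$n_valid_pairs %||% NA_integer_,
    parcel_ids = ids,
    class = c("ic_matrix", "matrix", "array")
  )
}

#' Write a gradient set as TSV plus JSON sidecar
#'
#' TSV columns `parcel_id`, `g1` ... `gK`; eigenvalues, variance ratios and
#' alignment metadata go to the sidecar.
#'
#' @param gradients a `gradient_set`.
#' @param path output TSV path.
#' @param meta extra sidecar entries.
#' @return `path`, invisibly.
#' @export
write_gradient_set <- function(gradients, path, meta = list()) {
  k <- ncol(gradients$scores)
  header <- paste(c("parcel_id", paste0("g", seq_len(k))), collapse = "\t")
  rows <- vapply(seq_len(nrow(gradients$scores)), function(i) {
    paste(c(i, fmt_num(gradients$scores[i, ])), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
  write_sidecar(path, c(meta, list(
    eigenvalues = gradients$eigenvalues,
    variance_ratio = gradients$variance_ratio,
    alignment = gradients$alignment,
    template_id = gradients$template_id,
    condition = gradients$condition,
    hash = hash(gradients$scores)
  )))
  invisible(path)
}

#' Write a 3-D/4-D array as NIfTI
#'
#' Thin wrapper over `RNifti::writeNifti()` with voxel size metadata.
#'
#' @param arr numeric or integer array.
#' @param path output `.nii.gz` path.
#' @param voxel_size_mm voxel edge lengths.
#' @return `path`, invisibly.
#' @export
write_volume <- function(arr, path, voxel_size_mm = c(3, 3, 3)) {
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- voxel_size_mm
  RNifti::writeNifti(img, path)
  invisible(path)
}
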