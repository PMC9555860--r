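#' Parcellation atlas
#'
#' A `parcellation_atlas` bundles everything the pipeline needs to know about
#' a brain parcellation: an integer label volume (0 = background, parcels
#' labelled by id), the ordered parcel ids, unit-sphere centroid coordinates
#' (used by the spin permutation test), network membership labels, and the
#' voxel size.
#'
#' Network labels follow the four functional networks contrasted in
#' gradient-difference analyses — `"semantic-not-control"`, `"SCN"` (semantic
#' control network), `"SCN+MDN"`, `"MDN"` (multiple-demand network) — plus
#' `"other"`; a parcel belongs to at most one of the four contrast networks.
#'
#' @param label_volume 3-D integer array; 0 is background.
#' @param parcel_ids ordered integer vector of parcel ids present in the
#'   volume.
#' @param centroids numeric matrix `P x 3` of unit-norm spherical centroid
#'   coordinates, rows in `parcel_ids` order.
#' @param network_labels character vector of length `P` (one of the four
#'   contrast networks or `"other"`).
#' @param voxel_size_mm positive length-3 numeric.
#' @return an object of class `parcellation_atlas`.
#' @seealso [load_atlas()], [make_synthetic_atlas()]
#' @export
parcellation_atlas <- function(label_volume, parcel_ids, centroids,
                               network_labels = NULL,
                               voxel_size_mm = c(3, 3, 3)) {
  label_volume <- as.array(label_volume)
  if (length(dim(label_volume)) != 3L) {
    abort("label_volume must be a 3-D array.")
  }
  if (any(label_volume != round(label_volume))) {
    abort("label_volume must be integer-valued (format error).")
  }
  storage.mode(label_volume) <- "integer"
  parcel_ids <- as.integer(parcel_ids)
  if (is.unsorted(parcel_ids, strictly = TRUE)) {
    o <- order(parcel_ids)
    parcel_ids <- parcel_ids[o]
    centroids <- centroids[o, , drop = FALSE]
    if (!is.null(network_labels)) network_labels <- network_labels[o]
  }
  present <- sort(unique(as.vector(label_volume)))
  present <- present[present != 0L]
  missing_lookup <- setdiff(present, parcel_ids)
  if (length(missing_lookup) > 0) {
    abort(paste0(
      "label volume contains parcel ", paste(missing_lookup, collapse = ", "),
      " absent from the lookup table."
    ))
  }
  absent_vol <- setdiff(parcel_ids, present)
  if (length(absent_vol) > 0) {
    abort(paste0(
      "parcel ", paste(absent_vol, collapse = ", "),
      " in the lookup table does not occur in the label volume."
    ))
  }
  centroids <- as.matrix(centroids)
  if (nrow(centroids) != length(parcel_ids) || ncol(centroids) != 3L) {
    abort("centroids must be a P x 3 matrix matching parcel_ids.")
  }
  norms <- sqrt(rowSums(centroids^2))
  if (any(abs(norms - 1) > 1e-6)) {
    abort("centroid coordinates must be unit-norm (within 1e-6).")
  }
  if (is.null(network_labels)) {
    network_labels <- rep("other", length(parcel_ids))
  }
  valid_nets <- c("semantic-not-control", "SCN", "SCN+MDN", "MDN", "other")
  if (!all(network_labels %in% valid_nets)) {
    abort(paste0(
      "unknown network label(s): ",
      paste(setdiff(network_labels, valid_nets), collapse = ", ")
    ))
  }
  if (any(voxel_size_mm <= 0) || length(voxel_size_mm) != 3L) {
    abort("voxel_size_mm must be a positive length-3 numeric.")
  }
  structure(
    list(
      label_volume = label_volume,
      parcel_ids = parcel_ids,
      centroids = centroids,
      network_labels = network_labels,
      voxel_size_mm = as.numeric(voxel_size_mm)
    ),
    class = "parcellation_atlas"
  )
}

#' @export
print.parcellation_atlas <- function(x, ...) {
  cat(
    "<parcellation_atlas> ", length(x$parcel_ids), " parcels, grid ",
    paste(dim(x$label_volume), collapse = "x"), ", networks: ",
    paste(names(table(x$network_labels)), collapse = ", "), "\n",
    sep = ""
  )
  invisible(x)
}

#' Number of parcels in an atlas
#' @param atlas a [parcellation_atlas()].
#' @return integer count of parcels.
#' @export
n_parcels <- function(atlas) length(atlas$parcel_ids)

#' Voxel-to-parcel assignment
#'
#' Linearises the label volume: returns, for each voxel belonging to a parcel
#' (non-zero label), its parcel id, named by the linear voxel index in the
#' grid.
#'
#' @param atlas a [parcellation_atlas()].
#' @return named integer vector, one element per in-parcel voxel.
#' @export
voxel_to_parcel <- function(atlas) {
  v <- as.vector(atlas$label_volume)
  idx <- which(v != 0L)
  setNames(v[idx], idx)
}

#' Load a parcellation atlas from disk
#'
#' Reads an integer NIfTI label volume plus two TSV tables keyed by
#' `parcel_id`: a lookup table (optional columns `name`, `network`) and a
#' centroid table (columns `x`, `y`, `z`, unit-sphere coordinates).
#'
#' @param label_volume_path path to a NIfTI (`.nii`/`.nii.gz`) integer label
#'   volume.
#' @param lookup_path path to a TSV with column `parcel_id` (and optionally
#'   `network`).
#' @param centroid_path path to a TSV with columns `parcel_id`, `x`, `y`, `z`.
#' @return a [parcellation_atlas()].
#' @export
load_atlas <- function(label_volume_path, lookup_path, centroid_path) {
  img <- RNifti::readNifti(label_volume_path)
  vol <- as.array(img)
  if (any(vol != round(vol))) {
    abort("label volume is not integer-valued (format error).")
  }
  lookup <- utils::read.delim(lookup_path, sep = "\t")
  if (!"parcel_id" %in% names(lookup)) abort("lookup TSV must have a parcel_id column.")
  cents <- utils::read.delim(centroid_path, sep = "\t")
  if (!all(c("parcel_id", "x", "y", "z") %in% names(cents))) {
    abort("centroid TSV must have columns parcel_id, x, y, z.")
  }
  ids <- sort(as.integer(lookup$parcel_id))
  cents <- cents[match(ids, cents$parcel_id), , drop = FALSE]
  if (any(is.na(cents$x))) abort("centroid table is missing parcels present in the lookup.")
  nets <- if ("network" %in% names(lookup)) {
    lookup$network[match(ids, lookup$parcel_id)]
  } else {
    NULL
  }
  pixdim <- attr(img, "pixdim") %||% c(3, 3, 3)
  parcellation_atlas(
    label_volume = vol,
    parcel_ids = ids,
    centroids = as.matrix(cents[, c("x", "y", "z")]),
    network_labels = nets,
    voxel_size_mm = pixdim[1:3]
  )
}

# Fibonacci lattice: n approximately evenly spaced points on the unit sphere,
# ordered by increasing z so parcel order tracks the sphere's long axis.
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 1
  z <- (2 * i + 1) / n - 1
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

#' Build a synthetic parcellation atlas
#'
#' Constructs a toy brain: parcels tile a compact 3-D grid (each parcel is a
#' near-cubic block of `voxels_per_parcel` voxels), and parcel centroids are
#' placed on the unit sphere by a Fibonacci lattice so that spin permutation
#' tests are well posed. Parcel order follows the sphere's z axis, which is
#' also the order of the default planted gradient, so the planted gradient is
#' spatially smooth on the sphere. Network labels are assigned from gradient
#' quantiles: the top decile plays the role of the semantic
#' (`"semantic-not-control"`) end, followed by `"SCN"`, `"SCN+MDN"` and
#' `"MDN"` deciles, with everything else `"other"`.
#'
#' @param n_parcels number of parcels (>= 2).
#' @param voxels_per_parcel voxels in each parcel block.
#' @param seed unused at present (the construction is deterministic); kept so
#'   the signature matches the other generators.
#' @return a [parcellation_atlas()].
#' @examples
#' atlas <- make_synthetic_atlas(n_parcels = 10, voxels_per_parcel = 8)
#' n_parcels(atlas)
#' @export
make_synthetic_atlas <- function(n_parcels, voxels_per_parcel = 20, seed = 1L) {
  if (n_parcels < 2) abort("n_parcels must be >= 2.")
  if (voxels_per_parcel < 2) abort("voxels_per_parcel must be >= 2.")
  pdims <- factor3(as.integer(n_parcels))
  bdims <- factor3(as.integer(voxels_per_parcel))
  grid_dim <- pdims * bdims
  vol <- array(0L, dim = grid_dim)
  pid <- 0L
  for (k in seq_len(pdims[3])) {
    for (j in seq_len(pdims[2])) {
      for (i in seq_len(pdims[1])) {
        pid <- pid + 1L
        xi <- ((i - 1L) * bdims[1] + 1L):(i * bdims[1])
        yi <- ((j - 1L) * bdims[2] + 1L):(j * bdims[2])
        zi <- ((k - 1L) * bdims[3] + 1L):(k * bdims[3])
        vol[xi, yi, zi] <- pid
      }
    }
  }
  cents <- fibonacci_sphere(n_parcels)
  if (n_parcels == 2) cents <- rbind(c(0, 0, -1), c(0, 0, 1))
  g <- seq(-1, 1, length.out = n_parcels)
  qr <- rank(-g, ties.method = "first") / n_parcels
  nets <- rep("other", n_parcels)
  nets[qr <= 0.1] <- "semantic-not-control"
  nets[qr > 0.1 & qr <= 0.2] <- "SCN"
  nets[qr > 0.2 & qr <= 0.3] <- "SCN+MDN"
  nets[qr > 0.3 & qr <= 0.4] <- "MDN"
  parcellation_atlas(
    label_volume = vol,
    parcel_ids = seq_len(n_parcels),
    centroids = cents,
    network_labels = nets,
    voxel_size_mm = c(3, 3, 3)
  )
}
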