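#' Row-wise sparsification of a connectivity matrix
#'
#' Keeps, in each row, only the strongest connections — the conventional
#' preprocessing before building a cosine affinity from a dense connectivity
#' matrix. The diagonal is excluded from the ranking and zeroed; each row
#' retains its `ceiling(density * (P - 1))` largest off-diagonal entries
#' (ties broken by first occurrence).
#'
#' @param m square numeric matrix.
#' @param density fraction of off-diagonal entries to keep, in (0, 1].
#' @return matrix of the same shape with weak entries zeroed.
#' @examples
#' sparsify_rows(matrix(c(0, .9, .5, .1, .9, 0, .2, .3,
#'   .5, .2, 0, .8, .1, .3, .8, 0), 4, 4), density = 0.5)
#' @export
sparsify_rows <- function(m, density = 0.1) {
  m <- as.matrix(m)
  p <- nrow(m)
  if (p != ncol(m)) abort("matrix must be square.")
  if (density <= 0 || density > 1) abort("density must be in (0, 1].")
  n_keep <- ceiling(density * (p - 1))
  out <- matrix(0, p, p, dimnames = dimnames(m))
  for (i in seq_len(p)) {
    row <- m[i, ]
    row[i] <- -Inf
    keep <- order(row, decreasing = TRUE)[seq_len(n_keep)]
    out[i, keep] <- m[i, keep]
  }
  diag(out) <- 0
  out
}

#' Cosine affinity between matrix rows
#'
#' Entry (i, j) is the cosine of rows i and j — the affinity kernel used
#' before PCA gradient decomposition. The result is symmetric with unit
#' diagonal.
#'
#' @param m numeric matrix (typically a sparsified connectivity matrix).
#' @return square affinity matrix.
#' @export
cosine_affinity <- function(m) {
  m <- as.matrix(m)
  nrm <- sqrt(rowSums(m^2))
  zero <- which(nrm == 0)
  if (length(zero) > 0) {
    abort(paste0("all-zero row(s) for parcel(s): ", paste(zero, collapse = ", ")))
  }
  a <- tcrossprod(m) / outer(nrm, nrm)
  a <- (a + t(a)) / 2
  diag(a) <- 1
  a
}

#' Gradient decomposition of an affinity matrix
#'
#' Principal component analysis of the (column-centred) affinity matrix:
#' each component ("gradient") assigns every parcel a score, components are
#' ordered by explained variance, and the first component is the principal
#' gradient. Component signs are fixed deterministically (first non-zero
#' loading positive); equal-eigenvalue ties keep the solver's order, which
#' is itself deterministic for a fixed input.
#'
#' @param affinity square symmetric matrix (tolerance `1e-8`).
#' @param n_components number of gradients to retain (<= P).
#' @param condition condition label stored on the result.
#' @return object of class `gradient_set`: list with `scores` (P x K),
#'   `eigenvalues`, `variance_ratio`, `alignment` (`"none"` until aligned),
#'   `template_id`, `condition`.
#' @seealso [align_gradients()], [gradient_difference()]
#' @export
decompose_gradients <- function(affinity, n_components = 10, condition = "all") {
  affinity <- as.matrix(unclass(affinity))
  p <- nrow(affinity)
  if (p != ncol(affinity)) abort("affinity must be square.")
  if (max(abs(affinity - t(affinity))) > 1e-8) {
    abort("affinity must be symmetric (beyond tolerance 1e-8).")
  }
  k <- min(n_components, p)
  pc <- prcomp(affinity, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  scores <- fix_signs(pc$x[, seq_len(k), drop = FALSE])
  total <- sum(ev)
  structure(
    list(
      scores = scores,
      eigenvalues = ev[seq_len(k)],
      variance_ratio = ev[seq_len(k)] / total,
      alignment = "none",
      template_id = NA_character_,
      condition = condition
    ),
    class = "gradient_set"
  )
}

#' @export
print.gradient_set <- function(x, ...) {
  cat(
    "<gradient_set> ", nrow(x$scores), " parcels x ", ncol(x$scores),
    " gradients (", x$condition, "); variance ratio: ",
    paste(sprintf("%.3f", head(x$variance_ratio, 3)), collapse = ", "),
    if (ncol(x$scores) > 3) ", ..." else "", "; alignment: ", x$alignment, "\n",
    sep = ""
  )
  invisible(x)
}

#' Align a gradient set to a template
#'
#' PCA components are defined only up to sign (and rotation among
#' equal-eigenvalue components), so condition-specific gradient sets must be
#' aligned to a common template before they can be compared or subtracted.
#' `"sign"` alignment (default) flips each component so its correlation with
#' the matched template component is non-negative; `"procrustes"` applies
#' the orthogonal rotation that best maps the scores onto the template.
#'
#' @param gradients a [decompose_gradients()] result.
#' @param template a `gradient_set` with at least as many components.
#' @param method `"sign"` or `"procrustes"`.
#' @param template_id label recorded in the alignment metadata.
#' @return the aligned `gradient_set`.
#' @export
align_gradients <- function(gradients, template,
                            method = c("sign", "procrustes"),
                            template_id = "template") {
  method <- match.arg(method)
  if (nrow(gradients$scores) != nrow(template$scores)) {
    abort("gradient and template parcel counts differ.")
  }
  k <- ncol(gradients$scores)
  if (ncol(template$scores) < k) abort("template has fewer components than input.")
  tpl <- template$scores[, seq_len(k), drop = FALSE]
  if (method == "sign") {
    for (j in seq_len(k)) {
      if (cor(gradients$scores[, j], tpl[, j]) < 0) {
        gradients$scores[, j] <- -gradients$scores[, j]
      }
    }
  } else {
    sv <- svd(crossprod(gradients$scores, tpl))
    rot <- sv$u %*% t(sv$v)
    gradients$scores <- gradients$scores %*% rot
  }
  gradients$alignment <- if (method == "sign") "sign-matched" else "procrustes"
  gradients$template_id <- template_id
  gradients
}

#' Condition difference of gradient scores
#'
#' Per-parcel difference of one gradient component between two conditions
#' (e.g. strong minus weak associations). Both inputs must have been aligned
#' to the same template — subtracting unaligned PCA scores is meaningless
#' under sign indeterminacy, so that is an error.
#'
#' @param grad_a,grad_b aligned `gradient_set`s sharing a template.
#' @param component which gradient to difference (default 1, the principal
#'   gradient).
#' @return tibble with `parcel`, `difference` (`grad_a` minus `grad_b`).
#' @export
gradient_difference <- function(grad_a, grad_b, component = 1) {
  if (grad_a$alignment == "none" || grad_b$alignment == "none") {
    abort("gradients must be aligned to a template before differencing.")
  }
  if (!identical(grad_a$template_id, grad_b$template_id)) {
    abort("gradients are aligned to different templates.")
  }
  if (nrow(grad_a$scores) != nrow(grad_b$scores)) abort("parcel counts differ.")
  tibble(
    parcel = seq_len(nrow(grad_a$scores)),
    difference = grad_a$scores[, component] - grad_b$scores[, component]
  )
}

#' Correlation between two parcel maps
#'
#' Pearson or Spearman correlation between two per-parcel maps, with a
#' parametric p value and, when sphere coordinates are supplied, a spin
#' permutation p value that respects spatial autocorrelation.
#'
#' @param map_a,map_b numeric vectors of equal length (>= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @param coords optional P x 3 unit-sphere centroids; triggers the spin
#'   test.
#' @param n_spin number of random rotations for the spin test.
#' @param seed rotation seed.
#' @return one-row tibble: `r`, `method`, `p_parametric`, `p_spin` (`NA`
#'   without coordinates), `n`.
#' @export
map_correlation <- function(map_a, map_b, method = c("pearson", "spearman"),
                            coords = NULL, n_spin = 5000, seed = 1L) {
  method <- match.arg(method)
  if (length(map_a) != length(map_b)) abort("maps differ in length.")
  if (length(map_a) < 3) abort("need at least 3 parcels.")
  if (sd(map_a) == 0 || sd(map_b) == 0) abort("zero-variance map.")
  ct <- suppressWarnings(cor.test(map_a, map_b, method = method))
  p_spin <- NA_real_
  if (!is.null(coords)) {
    p_spin <- spin_permutation_test(
      map_a, map_b, coords,
      n_perm = n_spin, seed = seed, method = method
    )$p_spin
  }
  tibble(
    r = unname(ct$estimate), method = method,
    p_parametric = ct$p.value, p_spin = p_spin, n = length(map_a)
  )
}

#' Full gradient pipeline for one connectivity matrix
#'
#' Convenience composition `sparsify_rows()` then `cosine_affinity()` then
#' [decompose_gradients()] with the customary defaults (row density 0.1,
#' 10 components).
#'
#' @param connectivity square connectivity matrix (e.g. an `ic_matrix`).
#' @param density row sparsity density.
#' @param n_components gradients to retain.
#' @param condition condition label.
#' @return a `gradient_set`.
#' @export
connectivity_gradients <- function(connectivity, density = 0.1,
                                   n_components = 10, condition = "all") {
  decompose_gradients(
    cosine_affinity(sparsify_rows(unclass(connectivity), density)),
    n_components = n_components, condition = condition
  )
}
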