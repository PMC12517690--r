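#' Extract masked voxel data from a NIfTI volume
#'
#' Reads a 3D or 4D NIfTI image and a 3D mask on the same grid, and returns
#' the masked values as a voxel x volume matrix together with a voxel table.
#' Voxels are taken in ascending linear-index order (x fastest), and
#' coordinates are millimetric world coordinates of the voxel centres via
#' the image affine; the order is stable across calls.
#'
#' @param volume Path to a 3D/4D NIfTI image.
#' @param mask Path to a 3D NIfTI mask (nonzero = inside); a label volume
#'   works too, labels are carried through.
#' @return A list with `values` (n_voxels x n_volumes matrix), `domain`
#'   (tibble: `voxel_id`, `i`, `j`, `k`, `x`, `y`, `z`, `label`).
#' @export
read_masked_volume <- function(volume, mask) {
  img <- RNifti::readNifti(volume)
  msk <- RNifti::readNifti(mask)
  di <- dim(img)
  dm <- dim(msk)
  if (length(dm) != 3) abort("mask must be a 3D volume.")
  if (!all(di[1:3] == dm)) abort("volume and mask grids differ.")
  if (max(abs(RNifti::xform(img) - RNifti::xform(msk))) > 1e-4) {
    abort("volume and mask affines differ.")
  }
  idx <- which(msk > 0)
  if (length(idx) == 0) abort("empty mask.")
  ijk <- arrayInd(idx, dm)
  xyz <- RNifti::voxelToWorld(ijk, msk)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, ncol = 3)
  nvol <- if (length(di) == 4) di[4] else 1L
  vals <- matrix(0, length(idx), nvol)
  for (t in seq_len(nvol)) {
    vol <- if (length(di) == 4) img[, , , t] else img
    vals[, t] <- vol[idx]
  }
  domain <- tibble::tibble(
    voxel_id = seq_along(idx),
    i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    label = as.vector(msk[idx])
  )
  list(values = vals, domain = domain)
}

#' Write per-voxel values back into a NIfTI volume
#'
#' Inverse of [read_masked_volume()]: paints a per-voxel vector into the
#' mask's grid (zero outside the mask) and writes it with the mask's affine.
#'
#' @param values Numeric vector, one value per mask voxel in scan order.
#' @param mask Path to the mask NIfTI defining grid, order and affine.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_masked_volume <- function(values, mask, path) {
  msk <- RNifti::readNifti(mask)
  idx <- which(msk > 0)
  if (length(values) != length(idx)) {
    abort("`values` must have one entry per mask voxel.")
  }
  out <- array(0, dim(msk))
  out[idx] <- values
  RNifti::writeNifti(RNifti::asNifti(out, reference = msk), path)
  invisible(path)
}

#' Write a synthetic voxel domain as a NIfTI label volume
#'
#' Rasterizes a [make_voxel_domain()] table onto a regular grid (one integer
#' label per nucleus, 0 outside) with a millimetric affine, so the synthetic
#' mask can round-trip through standard NIfTI tooling.
#'
#' @param domain A voxel-domain tibble.
#' @param path Output path.
#' @return `path` invisibly; label integers follow `levels(domain$nucleus)`.
#' @export
write_domain_nifti <- function(domain, path) {
  vs <- attr(domain, "voxel_size") %||% 2
  o <- c(min(domain$x), min(domain$y), min(domain$z))
  i <- round((domain$x - o[1]) / vs) + 1L
  j <- round((domain$y - o[2]) / vs) + 1L
  k <- round((domain$z - o[3]) / vs) + 1L
  arr <- array(0L, c(max(i), max(j), max(k)))
  arr[cbind(i, j, k)] <- as.integer(domain$nucleus)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- c(vs, vs, vs)
  mat <- diag(c(vs, vs, vs, 1))
  mat[1:3, 4] <- o - vs
  RNifti::qform(img) <- structure(mat, code = 2L)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Write a matrix as delimited text with a header row
#'
#' @param m Matrix (feature ids taken from column names when present).
#' @param path Output `.csv`/`.tsv` path.
#' @param ids Optional row identifier column (e.g. voxel ids).
#' @return `path`, invisibly.
#' @export
write_matrix_table <- function(m, path, ids = NULL) {
  m <- as.matrix(m)
  df <- tibble::as_tibble(m, .name_repair = "unique_quiet")
  if (is.null(colnames(m))) names(df) <- paste0("f", seq_len(ncol(m)))
  if (!is.null(ids)) df <- dplyr::bind_cols(tibble::tibble(id = ids), df)
  readr::write_csv(df, path)
  invisible(path)
}

#' Read a matrix written by [write_matrix_table()]
#'
#' @param path Delimited text path.
#' @param has_ids Whether the first column holds row ids.
#' @return A numeric matrix (ids, if any, as rownames).
#' @export
read_matrix_table <- function(path, has_ids = FALSE) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (has_ids) {
    ids <- df[[1]]
    df <- df[, -1]
    m <- as.matrix(df)
    rownames(m) <- as.character(ids)
    m
  } else {
    as.matrix(df)
  }
}
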