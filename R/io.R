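# Slice and volume i/o: 8-bit grayscale PNG (one file per slice), NIfTI
# volumes, and the plain-text dataset manifest.

round_half_up <- function(x) floor(x + 0.5)

#' Read and write 8-bit grayscale slices
#'
#' Slices are numeric matrices with values in \eqn{[0, 255]}.  On write,
#' values are quantized with round-half-up to integers; in memory full
#' precision is kept.
#'
#' @param slice Numeric matrix in \eqn{[0, 255]}.
#' @param path File path.
#' @return `read_gray_png` returns a numeric matrix in \eqn{[0, 255]};
#'   `write_gray_png` returns `path` invisibly.
#' @export
write_gray_png <- function(slice, path) {
  if (any(slice < 0 | slice > 255)) {
    validation_error("slice values outside [0, 255]")
  }
  png::writePNG(round_half_up(slice) / 255, target = path)
  invisible(path)
}

#' @rdname write_gray_png
#' @export
read_gray_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  img * 255
}

#' Read and write NIfTI volumes
#'
#' @param voxels 3D numeric array (rows, columns, slices).
#' @param path File path (`.nii` or `.nii.gz`).
#' @param spacing Voxel spacing in mm, length 3, all positive.
#' @return `read_nifti_volume` returns a list with `voxels` (3D array) and
#'   `spacing`; `write_nifti_volume` returns `path` invisibly.
#' @export
write_nifti_volume <- function(voxels, path, spacing = c(1, 1, 1)) {
  if (any(spacing <= 0)) validation_error("spacing components must be > 0")
  img <- RNifti::asNifti(voxels, pixdim = spacing)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_nifti_volume
#' @export
read_nifti_volume <- function(path) {
  img <- RNifti::readNifti(path)
  vox <- as.array(img)
  if (length(dim(vox)) == 2L) vox <- array(vox, c(dim(vox), 1L))
  list(voxels = vox, spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' Write a phantom dataset to disk
#'
#' Writes one grayscale PNG per slice plus a tab-separated manifest
#' (`manifest.tsv`: role, subject id, slice index, file path).  With
#' `nifti = TRUE` the paired slices are additionally stacked into CT/MR
#' NIfTI volumes.
#'
#' @param dataset A `ctmr_phantom_dataset`.
#' @param dir Output directory (created if absent).
#' @param nifti Also export paired stacks as NIfTI volumes.
#' @return The manifest tibble with file paths filled in, invisibly.
#' @export
write_phantom_dataset <- function(dataset, dir, nifti = FALSE) {
  stopifnot(inherits(dataset, "ctmr_phantom_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (i in seq_along(dataset$paired)) {
    p <- dataset$paired[[i]]
    ct_path <- file.path(dir, sprintf("paired_%03d_ct.png", i))
    mr_path <- file.path(dir, sprintf("paired_%03d_mr.png", i))
    write_gray_png(p$ct, ct_path)
    write_gray_png(p$mr, mr_path)
    paths <- c(paths, ct_path, mr_path)
  }
  for (i in seq_along(dataset$unpaired_ct)) {
    pth <- file.path(dir, sprintf("unpaired_ct_%03d.png", i))
    write_gray_png(dataset$unpaired_ct[[i]], pth)
    paths <- c(paths, pth)
  }
  for (i in seq_along(dataset$unpaired_mr)) {
    pth <- file.path(dir, sprintf("unpaired_mr_%03d.png", i))
    write_gray_png(dataset$unpaired_mr[[i]], pth)
    paths <- c(paths, pth)
  }
  manifest <- dataset$manifest
  manifest$file_path <- paths
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (nifti && length(dataset$paired) > 0) {
    ct_stack <- simplify2array(lapply(dataset$paired, `[[`, "ct"))
    mr_stack <- simplify2array(lapply(dataset$paired, `[[`, "mr"))
    write_nifti_volume(ct_stack, file.path(dir, "paired_ct.nii.gz"))
    write_nifti_volume(mr_stack, file.path(dir, "paired_mr.nii.gz"))
  }
  invisible(manifest)
}

#' Load a slice dataset from a manifest directory
#'
#' Reads the `manifest.tsv` written by [write_phantom_dataset()] and loads
#' the referenced PNG slices back into the in-memory dataset layout used by
#' [train()].
#'
#' @param dir Dataset directory containing `manifest.tsv`.
#' @return A list with `paired` (list of `ctmr_paired_sample`),
#'   `unpaired_ct`, `unpaired_mr` and the manifest tibble.
#' @export
load_slice_dataset <- function(dir) {
  mf_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(mf_path)) {
    data_error(sprintf("no manifest.tsv in '%s'", dir))
  }
  manifest <- tibble::as_tibble(
    utils::read.table(mf_path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  )
  load_one <- function(row) read_gray_png(row$file_path)
  paired_ids <- unique(manifest$subject_id[manifest$role == "paired_ct"])
  paired <- lapply(seq_along(paired_ids), function(i) {
    sid <- paired_ids[i]
    ct_row <- manifest[manifest$role == "paired_ct" &
                         manifest$subject_id == sid, ][1, ]
    mr_row <- manifest[manifest$role == "paired_mr" &
                         manifest$subject_id == sid, ][1, ]
    structure(list(ct = load_one(ct_row), mr = load_one(mr_row),
                   subject_id = sid,
                   slice_index = as.integer(ct_row$slice_index)),
              class = "ctmr_paired_sample")
  })
  get_pool <- function(role) {
    rows <- manifest[manifest$role == role, ]
    lapply(seq_len(nrow(rows)), function(i) load_one(rows[i, ]))
  }
  list(paired = paired, unpaired_ct = get_pool("unpaired_ct"),
       unpaired_mr = get_pool("unpaired_mr"), manifest = manifest)
}
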