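# Lightweight I/O: property tables and result tables as CSV, image maps as
# NIfTI (via RNifti), configuration/manifest as JSON.

#' Write an image map as NIfTI
#'
#' @param image matrix (or list of matrices written as volumes along the
#'   third dimension).
#' @param path output file (`.nii` / `.nii.gz`).
#' @param pixel_mm in-plane pixel size, mm.
#' @param slice_mm slice thickness, mm.
#' @return the path, invisibly.
#' @export
write_map_nifti <- function(image, path, pixel_mm = 3, slice_mm = 3) {
  arr <- if (is.list(image))
    array(unlist(image), c(dim(image[[1]]), length(image)))
  else array(image, c(dim(image), 1))
  img <- RNifti::asNifti(arr, pixdim = c(pixel_mm, pixel_mm, slice_mm))
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a NIfTI map written by [write_map_nifti()]
#'
#' @param path file path.
#' @return matrix (single volume) or list of matrices.
#' @export
read_map_nifti <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  if (length(dim(arr)) == 2L) return(arr)
  if (dim(arr)[3] == 1L) return(arr[, , 1])
  lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
}

#' Write the tissue property table as CSV
#'
#' @param phantom a phantom.
#' @param path output CSV.
#' @return the path, invisibly.
#' @export
write_property_table <- function(phantom, path) {
  utils::write.csv(phantom$properties, path, row.names = FALSE)
  invisible(path)
}

#' Write study outputs to a directory
#'
#' ROI summary and per-voxel fits as CSV, ST K1 map and per-study mean K1
#' maps as NIfTI, and a JSON manifest (config hash, seed, scale, versions).
#'
#' @param study a `pet_mc_study`.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study_outputs <- function(study, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(study$roi_summary, file.path(outdir, "roi_summary.csv"),
                   row.names = FALSE)
  fits <- dplyr::bind_rows(lapply(names(study$fits), function(s)
    dplyr::bind_rows(lapply(seq_along(study$fits[[s]]), function(r)
      dplyr::mutate(study$fits[[s]][[r]], study = s, realization = r)))))
  utils::write.csv(fits, file.path(outdir, "voxel_fits.csv"),
                   row.names = FALSE)
  h <- study$phantom$pixel_size; sl <- study$phantom$slice_thickness
  write_map_nifti(study$st_k1_map, file.path(outdir, "k1_ST.nii.gz"), h, sl)
  for (s in names(study$k1_maps)) {
    stack <- study$k1_maps[[s]]
    mean_map <- Reduce(`+`, lapply(stack, function(m) {
      m[is.na(m)] <- 0; m
    })) / length(stack)
    mean_map[!study$mask] <- NA
    write_map_nifti(mean_map,
                    file.path(outdir, sprintf("k1_mean_%s.nii.gz", s)), h, sl)
  }
  write_property_table(study$phantom, file.path(outdir, "tissue_properties.csv"))
  jsonlite::write_json(study$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
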