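# NIfTI volume IO (via RNifti) and dataset manifests. Volumes are stored
# float32 on disk; metric computation stays in double precision.

#' Read a 3D NIfTI volume
#'
#' @param path Path to a `.nii` / `.nii.gz` file.
#' @return List with `values` (3D double array) and `voxel_size_mm`
#'   (first spatial pixdim).
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop_mugen("file not found: ", path)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop_mugen("malformed NIfTI file ",
                                                 path, ": ", conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) != 3L)
    stop_mugen("expected a 3D volume but ", path, " has ",
               length(dim(arr)), " dimensions")
  list(values = array(as.double(arr), dim(arr)),
       voxel_size_mm = RNifti::pixdim(img)[1])
}

#' Write a 3D volume as NIfTI (float32)
#'
#' @param values 3D numeric array (or object with a `values` field).
#' @param voxel_size_mm Isotropic voxel size recorded in the header.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(values, voxel_size_mm, path) {
  values <- vol_values(values)
  check_volume(values, "values")
  img <- RNifti::asNifti(values)
  RNifti::pixdim(img) <- rep(voxel_size_mm, 3)
  RNifti::writeNifti(img, path, datatype = "float")
  invisible(path)
}

#' Read a dataset manifest
#'
#' @param path Path to a tab-separated manifest written by
#'   [make_dataset()].
#' @param split Optional filter (`"train"`, `"validation"`, `"test"`).
#' @return data.frame.
#' @export
read_manifest <- function(path, split = NULL) {
  m <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("case_id", "split", "contrast", "path_primary", "path_scatter",
            "path_mu", "path_labels")
  if (!all(need %in% names(m)))
    stop_mugen("manifest is missing columns: ",
               paste(setdiff(need, names(m)), collapse = ", "))
  if (!is.null(split)) m <- m[m$split == split, , drop = FALSE]
  m
}

#' Load manifest cases into memory
#'
#' @param manifest data.frame from [read_manifest()].
#' @return List of raw cases (`pair`, `mu`, `labels`, `contrast`) matching
#'   the [make_training_pairs()] layout.
#' @export
load_cases <- function(manifest) {
  lapply(seq_len(nrow(manifest)), function(i) {
    r <- manifest[i, ]
    p <- read_volume(r$path_primary)
    s <- read_volume(r$path_scatter)
    mu <- read_volume(r$path_mu)
    lb <- read_volume(r$path_labels)
    list(pair = structure(list(primary = p$values, scatter = s$values,
                               voxel_size_mm = p$voxel_size_mm),
                          class = "spect_pair"),
         mu = new_mu_map(mu$values, mu$voxel_size_mm, "ground_truth"),
         labels = structure(list(values = array(as.integer(round(lb$values)),
                                                dim(lb$values)),
                                 classes = LABEL_CODES), class = "label_map"),
         contrast = as.logical(r$contrast))
  })
}
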