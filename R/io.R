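#' Read imaging or tabular data with design and contrast
#'
#' Accepts a 4-D NIfTI image (N volumes) or a CSV data matrix (N rows),
#' together with headerless CSV design and contrast matrices and an
#' optional binary NIfTI mask. Imaging data are flattened to an N x V
#' matrix over in-mask voxels, retaining the mapping back to the grid;
#' CSV input has no grid, so spatial statistics are unavailable (a
#' warning notes this when a mask is also absent).
#'
#' @param data path to a 4-D NIfTI (.nii/.nii.gz) or CSV file.
#' @param design path to the design matrix CSV (N rows).
#' @param contrast path to the contrast CSV (rows = contrast rows).
#' @param mask optional path to a 3-D binary NIfTI mask.
#' @param header logical: CSV files carry a header row.
#' @return list with \code{Y} (N x V, attribute \code{grid} when
#'   imaging), \code{M}, \code{C}, \code{grid}, \code{mask_idx}
#'   (in-mask linear voxel indices), and \code{template} (the RNifti
#'   image carrying the affine, when imaging).
#' @export
read_inputs <- function(data, design, contrast, mask = NULL,
                        header = FALSE) {
  M <- read_matrix_csv(design, header)
  C <- read_matrix_csv(contrast, header)
  if (ncol(C) == 1 && nrow(C) == ncol(M)) C <- C  # column contrast
  else if (nrow(C) != ncol(M)) C <- t(C)
  is_nifti <- grepl("\\.nii(\\.gz)?$", data, ignore.case = TRUE)
  if (is_nifti) {
    img <- RNifti::readNifti(data)
    dm <- dim(img)
    if (length(dm) != 4)
      stop("imaging input must be 4-D (spatial grid x N volumes)")
    grid <- dm[1:3]
    N <- dm[4]
    vol <- matrix(as.vector(img), prod(grid), N)
    mask_idx <- seq_len(prod(grid))
    if (!is.null(mask)) {
      mk <- RNifti::readNifti(mask)
      if (!all(dim(mk)[1:3] == grid))
        stop("mask grid ", paste(dim(mk)[1:3], collapse = "x"),
             " does not match data grid ", paste(grid, collapse = "x"))
      mask_idx <- which(as.vector(mk) != 0)
    }
    Y <- t(vol[mask_idx, , drop = FALSE])
    if (is.null(mask)) attr(Y, "grid") <- grid
    template <- img
  } else {
    Y <- read_matrix_csv(data, header)
    grid <- NULL; mask_idx <- NULL; template <- NULL
    if (!is.null(mask))
      warning("mask ignored for tabular input")
    message("tabular input: spatial statistics unavailable (no grid)")
  }
  if (nrow(Y) != nrow(M))
    stop("data has ", nrow(Y), " observations but the design has ",
         nrow(M), " rows")
  list(Y = Y, M = M, C = C, grid = grid, mask_idx = mask_idx,
       template = template)
}

#' Write p-value maps and tables
#'
#' Writes each p-vector as a NIfTI map (when grid metadata are present)
#' encoded as 1 - p (default; larger = more significant) and optionally
#' -log10(p), plus a CSV table of all vectors, and a machine-readable
#' provenance record (configuration, seed, package version) alongside
#' the outputs. Out-of-mask voxels are written as zero.
#'
#' @param pmaps named list of p-value vectors.
#' @param prefix output path prefix.
#' @param grid integer grid dimensions, or NULL for tabular output
#'   only.
#' @param mask_idx in-mask linear indices (defaults to the full grid).
#' @param template optional RNifti image supplying the affine.
#' @param logp also write -log10(p) maps.
#' @param config list recorded in the provenance file.
#' @return invisibly, the paths written.
#' @export
write_results <- function(pmaps, prefix, grid = NULL, mask_idx = NULL,
                          template = NULL, logp = FALSE, config = NULL) {
  paths <- character(0)
  tab <- as.data.frame(pmaps)
  csv <- paste0(prefix, "_pvalues.csv")
  utils::write.csv(tab, csv, row.names = FALSE)
  paths <- c(paths, csv)
  if (!is.null(grid)) {
    if (is.null(mask_idx)) mask_idx <- seq_len(prod(grid))
    for (nm in names(pmaps)) {
      vol <- array(0, grid)
      vol[mask_idx] <- 1 - pmaps[[nm]]
      f <- paste0(prefix, "_", nm, "_1mp.nii.gz")
      write_nifti_like(vol, f, template)
      paths <- c(paths, f)
      if (logp) {
        vol[mask_idx] <- -log10(pmaps[[nm]])
        f <- paste0(prefix, "_", nm, "_logp.nii.gz")
        write_nifti_like(vol, f, template)
        paths <- c(paths, f)
      }
    }
  }
  prov <- list(package = "permaccel",
               version = as.character(utils::packageVersion("permaccel")),
               timestamp = format(Sys.time(), tz = "UTC"),
               config = config)
  provf <- paste0(prefix, "_provenance.json")
  jsonlite::write_json(prov, provf, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  paths <- c(paths, provf)
  invisible(paths)
}

write_nifti_like <- function(vol, path, template = NULL) {
  img <- if (!is.null(template))
    RNifti::asNifti(vol, reference = template) else RNifti::asNifti(vol)
  RNifti::writeNifti(img, path)
}
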