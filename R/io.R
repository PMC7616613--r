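# Format adapters. Label maps round-trip integer-exactly (PNG 8-bit, NIfTI,
# MetaImage); images round-trip within float precision (NIfTI/MetaImage) or
# 8-bit quantisation (PNG). The MetaImage reader/writer exists for
# compatibility with CAMUS-style .mhd/.mha archives; it is a plain
# ASCII-header + raw-block format.

format_of <- function(path) {
  if (grepl("\\.png$", path)) "png"
  else if (grepl("\\.nii(\\.gz)?$", path)) "nifti"
  else if (grepl("\\.mha$", path)) "metaimage"
  else if (grepl("\\.csv$", path)) "csv"
  else abort(sprintf("unsupported file format: %s", path))
}

#' Write / read a label map (PNG, NIfTI or MetaImage)
#'
#' PNG stores the raw integer codes in an 8-bit single channel; NIfTI and
#' MetaImage store them losslessly. Reading validates the class inventory
#' against [echo_classes()] and errors listing any unknown code.
#'
#' @param labels A `label_map`.
#' @param path Destination; format inferred from the extension
#'   (`.png`, `.nii`/`.nii.gz`, `.mha`).
#' @export
write_label_map <- function(labels, path) {
  switch(format_of(path),
         png = png::writePNG(unclass(labels) / 255, path),
         nifti = RNifti::writeNifti(RNifti::asNifti(unclass(labels) * 1), path),
         metaimage = write_mha(unclass(labels), path, type = "MET_UCHAR"),
         abort("label maps support png/nifti/metaimage only."))
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  m <- switch(format_of(path),
              png = round(png::readPNG(path) * 255),
              nifti = round(as.matrix(RNifti::readNifti(path))[, ]),
              metaimage = round(read_mha(path)),
              abort("label maps support png/nifti/metaimage only."))
  if (length(dim(m)) > 2) m <- m[, , 1]
  unknown <- setdiff(unique(as.vector(m)), echo_classes())
  if (length(unknown)) {
    abort(sprintf("read_label_map: unknown class value(s): %s",
                  paste(sort(unknown), collapse = ", ")))
  }
  as_label_map(matrix(as.integer(m), nrow(m), ncol(m)))
}

#' Write / read an echo image (PNG, NIfTI or MetaImage)
#'
#' PNG quantises unit-scale intensities to 8 bits; NIfTI and MetaImage keep
#' float precision.
#'
#' @param img An `echo_image` (unit scale for PNG).
#' @param path Destination path.
#' @export
write_echo_image <- function(img, path) {
  m <- unclass(img)
  switch(format_of(path),
         png = png::writePNG(pmin(pmax(m, 0), 1), path),
         nifti = RNifti::writeNifti(RNifti::asNifti(m), path,
                                    datatype = "double"),
         metaimage = write_mha(m, path, type = "MET_DOUBLE"),
         abort("images support png/nifti/metaimage only."))
  invisible(path)
}

#' @rdname write_echo_image
#' @export
read_echo_image <- function(path) {
  m <- switch(format_of(path),
              png = png::readPNG(path),
              nifti = as.matrix(RNifti::readNifti(path))[, ],
              metaimage = read_mha(path),
              abort("images support png/nifti/metaimage only."))
  if (length(dim(m)) > 2) m <- m[, , 1]
  structure(matrix(as.numeric(m), nrow(m), ncol(m)),
            class = c("echo_image", "matrix", "array"))
}

# minimal MetaImage (.mha, local raw block) writer/reader; 2D only.
# Elements are stored x-fastest (columns), so the matrix is transposed on
# write and restored on read.
write_mha <- function(m, path, type = c("MET_DOUBLE", "MET_UCHAR")) {
  type <- match.arg(type)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ObjectType = Image",
           "NDims = 2",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           sprintf("DimSize = %d %d", ncol(m), nrow(m)),
           sprintf("ElementType = %s", type),
           "ElementDataFile = LOCAL")
  writeLines(hdr, con)
  v <- as.vector(t(m))
  if (type == "MET_UCHAR") {
    writeBin(as.raw(as.integer(v)), con)
  } else {
    writeBin(as.numeric(v), con, size = 8)
  }
  invisible(path)
}

read_mha <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  repeat {
    line <- readLines(con, n = 1)
    kv <- strsplit(line, " = ", fixed = TRUE)[[1]]
    hdr[[kv[1]]] <- kv[2]
    if (kv[1] == "ElementDataFile") break
  }
  dims <- as.integer(strsplit(hdr$DimSize, " ")[[1]])
  n <- prod(dims)
  v <- switch(hdr$ElementType,
              MET_UCHAR = as.numeric(readBin(con, "raw", n)),
              MET_DOUBLE = readBin(con, "numeric", n, size = 8),
              MET_FLOAT = readBin(con, "numeric", n, size = 4),
              abort(sprintf("unsupported ElementType %s", hdr$ElementType)))
  t(matrix(v, dims[1], dims[2]))
}

#' Write / read a dataset manifest CSV
#' @param manifest A tibble.
#' @param path CSV path.
#' @export
write_manifest <- function(manifest, path) {
  readr::write_csv(manifest, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  readr::read_csv(path, show_col_types = FALSE)
}

#' Export a phantom dataset to disk
#'
#' Writes per-sample label maps and images in the requested format plus a
#' manifest CSV (`case_id, view, phase, label_path, image_path, seed`).
#'
#' @param data A `phantom_dataset`.
#' @param dir Output directory.
#' @param format `"png"`, `"nifti"` or `"metaimage"`.
#' @return The manifest tibble (invisibly).
#' @export
export_phantom_dataset <- function(data, dir, format = c("png", "nifti", "metaimage")) {
  format <- match.arg(format)
  ext <- switch(format, png = ".png", nifti = ".nii.gz", metaimage = ".mha")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(data$samples, function(s) {
    stem <- sprintf("case%03d_%s_%s", s$meta$case_id, s$meta$view, s$meta$phase)
    lp <- file.path(dir, paste0(stem, "_label", ext))
    ip <- file.path(dir, paste0(stem, "_image", ext))
    write_label_map(s$label_map, lp)
    write_echo_image(s$image, ip)
    tibble::tibble(case_id = s$meta$case_id, view = s$meta$view,
                   phase = s$meta$phase, label_path = lp, image_path = ip,
                   seed = s$meta$seed)
  })
  manifest <- dplyr::bind_rows(rows)
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}
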