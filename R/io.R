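# Raster and table I/O. Label masks are single-channel 8-bit PNG or 8/16-bit
# TIFF; both round-trip labels losslessly (PNG up to 255, TIFF up to 65535).
# PNG reading also accepts 16-bit files.

MASK_MAX_16 <- 65535L

#' Read a label mask from a PNG or TIFF file
#'
#' @param path file path; format chosen by extension (.png, .tif/.tiff).
#' @return integer matrix of labels.
#' @export
readMask <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    img <- png::readPNG(path, info = TRUE)
    depth <- attr(img, "info")$bit.depth
  } else if (ext %in% c("tif", "tiff")) {
    img <- tiff::readTIFF(path, info = TRUE)
    depth <- attr(img, "bits.per.sample")
  } else {
    stop(sprintf("unsupported mask format '%s' (use png or tiff)", ext))
  }
  if (length(dim(img)) == 3L)
    stop("mask must be a single-channel raster (got a multi-channel image)")
  # readers scale to [0,1] by the file's own bit depth
  m <- round(img * (2^depth - 1))
  storage.mode(m) <- "integer"
  attributes(m) <- list(dim = dim(img))   # drop reader metadata
  m
}

#' Write a label mask
#'
#' Labels up to 255 may be written as 8-bit PNG; larger labels (up to 65535)
#' require TIFF, written with 16 bits per sample. Round-trips losslessly with
#' \code{\link{readMask}}.
#'
#' @param mask integer matrix of labels (0 = background).
#' @param path output path ending in .png or .tif/.tiff.
#' @return \code{path}, invisibly.
#' @export
writeMask <- function(mask, path) {
  stopifnot(is.matrix(mask), all(mask >= 0))
  ext <- tolower(tools::file_ext(path))
  mx <- max(mask)
  if (mx > MASK_MAX_16) stop("labels exceed 65535")
  if (ext == "png") {
    if (mx > 255L)
      stop("labels exceed 255: write a 16-bit TIFF (.tif) instead")
    png::writePNG(mask / 255, path)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(mask / MASK_MAX_16, path, bits.per.sample = 16L)
  } else {
    stop(sprintf("unsupported mask format '%s' (use png or tiff)", ext))
  }
  invisible(path)
}

#' Write / read a per-vertebra truth table
#'
#' Schema: level, ha, hm, hp, kind, acute (one row per vertebra; kind is the
#' comma-joined deformity kinds or "none").
#'
#' @param phantom a \linkS4class{SpinePhantom}.
#' @param path CSV path.
#' @return the table (invisibly for the writer).
#' @export
writePhantomTruth <- function(phantom, path) {
  spec <- phantom@spec
  kinds <- vapply(seq_along(polygons(phantom)), function(k) {
    kk <- vapply(Filter(function(d) d@level == k, spec@deformities),
                 function(d) d@kind, "")
    if (length(kk)) paste(kk, collapse = ",") else "none"
  }, "")
  h <- trueHeights(phantom)
  tab <- data.frame(level = seq_len(nrow(h)), ha = h[, "ha"], hm = h[, "hm"],
                    hp = h[, "hp"], kind = kinds, acute = truthAcute(phantom))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

VERTEBRA_TABLE_CORE <- c("level", "ha", "hm", "hp", "hlr", "grade",
                         "vcf_flag", "truth_acute")

#' Write / read the combined vertebra table
#'
#' Core schema: level, ha, hm, hp, hlr, grade, vcf_flag, truth_acute, plus
#' one positive/score column pair per detector and per fusion result. HLR is
#' rounded half-up to 2 decimals on write (full precision is internal).
#'
#' @param tab data.frame following the schema.
#' @param path CSV path.
#' @return \code{path} invisibly (writer); validated data.frame (reader).
#' @export
writeVertebraTable <- function(tab, path) {
  stopifnot(all(VERTEBRA_TABLE_CORE %in% names(tab)))
  tab$hlr <- roundHalfUp(tab$hlr, 2)
  num <- vapply(tab, is.numeric, TRUE) & !(names(tab) %in% c("level"))
  tab[num] <- lapply(tab[num], roundHalfUp, 4)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeVertebraTable
#' @export
readVertebraTable <- function(path) {
  tab <- utils::read.csv(path)
  missing <- setdiff(VERTEBRA_TABLE_CORE, names(tab))
  if (length(missing))
    stop(sprintf("vertebra table lacks required columns: %s",
                 paste(missing, collapse = ", ")))
  tab
}

#' Read a run configuration
#'
#' YAML mapping with the keys understood by \code{\link{runExperiment}}.
#'
#' @param path YAML file path.
#' @return named list.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  yaml::read_yaml(path)
}
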