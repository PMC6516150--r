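## CSV and image I/O. All tabular formats are plain RFC-4180 CSV with
## the column schemas documented on each reader.

.requireCols <- function(df, cols, path) {
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop("missing column(s) ", paste(miss, collapse = ", "), " in ", path)
}

#' Read wire-myography recordings
#'
#' Schema: `segment_id`, `segment_length_mm`, `step`, `diameter_um`,
#' and either `tension_mN_per_mm` or `force_mN` (converted with
#' [tensionFromForce()]). Additional columns (e.g. `genotype`,
#' `treatment`) are kept as metadata.
#'
#' @param path CSV file.
#' @return named list of \linkS4class{WireMyoCurve}.
#' @export
readWireCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireCols(df, c("segment_id", "segment_length_mm", "step",
                     "diameter_um"), path)
  if (!("tension_mN_per_mm" %in% names(df)) &&
      !("force_mN" %in% names(df)))
    stop("need tension_mN_per_mm or force_mN in ", path)
  extra <- setdiff(names(df), c("segment_id", "segment_length_mm",
                                "step", "diameter_um",
                                "tension_mN_per_mm", "force_mN"))
  out <- lapply(split(df, df$segment_id), function(d) {
    d <- d[order(d$step), ]
    tn <- if ("tension_mN_per_mm" %in% names(d)) d$tension_mN_per_mm
          else tensionFromForce(d$force_mN, d$segment_length_mm[1])
    new("WireMyoCurve", segmentId = as.character(d$segment_id[1]),
        segmentLength = d$segment_length_mm[1],
        diameter = d$diameter_um, tension = tn,
        metadata = as.list(d[1, extra, drop = FALSE]))
  })
  out[order(names(out))]
}

#' Read passive pressure-myography series
#'
#' Schema: `animal_id`, `pressure_mmHg`, `di_um`, `de_um`; extra
#' columns become metadata.
#'
#' @param path CSV file.
#' @return named list of \linkS4class{PressureDiameterSeries}.
#' @export
readPressureCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireCols(df, c("animal_id", "pressure_mmHg", "di_um", "de_um"),
               path)
  extra <- setdiff(names(df), c("animal_id", "pressure_mmHg", "di_um",
                                "de_um"))
  out <- lapply(split(df, df$animal_id), function(d) {
    d <- d[order(d$pressure_mmHg), ]
    new("PressureDiameterSeries", animalId = as.character(d$animal_id[1]),
        pressure = d$pressure_mmHg, innerDiameter = d$di_um,
        outerDiameter = d$de_um,
        metadata = as.list(d[1, extra, drop = FALSE]))
  })
  out[order(names(out))]
}

#' Read MRI lumen-area time curves
#'
#' Schema: `animal_id`, `slice_id`, `time_ms`, `area_mm2`; optional
#' `heart_period_ms`; extra columns become metadata.
#'
#' @param path CSV file.
#' @return nested list: per animal, per slice, an
#'   \linkS4class{AreaTimeCurve}.
#' @export
readAreaCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireCols(df, c("animal_id", "slice_id", "time_ms", "area_mm2"),
               path)
  lapply(split(df, df$animal_id), function(d) {
    lapply(split(d, d$slice_id), function(s) {
      s <- s[order(s$time_ms), ]
      hp <- if ("heart_period_ms" %in% names(s)) s$heart_period_ms[1]
            else NA_real_
      new("AreaTimeCurve", animalId = as.character(s$animal_id[1]),
          sliceId = as.character(s$slice_id[1]), time = s$time_ms,
          area = s$area_mm2, heartPeriod = hp)
    })
  })
}

#' Read pulse-wave-velocity records
#'
#' Schema: `animal_id`, `distance_mm`, `t_aorta_ms`, `t_femoral_ms`,
#' plus any group columns.
#'
#' @param path CSV file.
#' @return the data.frame, validated.
#' @export
readPWVCSV <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  .requireCols(df, c("animal_id", "distance_mm", "t_aorta_ms",
                     "t_femoral_ms"), path)
  df
}

#' Read a grayscale image as a numeric matrix
#'
#' Wraps EBImage for 8/16-bit grayscale TIFF/PNG; multi-channel images
#' are averaged to grayscale. Returns intensities in [0, 1].
#'
#' @param path image file.
#' @return numeric matrix indexed [x, y].
#' @export
readGrayImage <- function(path) {
  img <- EBImage::readImage(path)
  d <- EBImage::imageData(img)
  if (length(dim(d)) == 3L) d <- apply(d, c(1, 2), mean)
  d
}

#' Write a grayscale matrix as a 16-bit TIFF
#'
#' Intensities are scaled to the [0, 1] range of the file format by the
#' matrix maximum (or an explicit `scale`).
#'
#' @param img numeric matrix.
#' @param path output file ('.tif').
#' @param scale divisor mapping intensities into [0, 1]; default
#'   max(img).
#' @export
writeGrayTiff <- function(img, path, scale = NULL) {
  if (is.null(scale)) scale <- max(img, 1e-12)
  EBImage::writeImage(EBImage::Image(pmin(pmax(img / scale, 0), 1)),
                      path, type = "tiff", bits.per.sample = 16L)
  invisible(path)
}
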