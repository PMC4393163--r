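#' Catalog of the 73 sway indices
#'
#' One row per index: number, name, channel (\code{"planar"}, \code{"ml"},
#' \code{"ap"} or \code{""} when not applicable), whether the raw value is
#' log10-transformed before standardization (all indices whose conventional
#' name carries a \code{log-} prefix), and the behaviour of the raw value
#' under uniform spatial scaling of the trajectory by a factor c:
#' \describe{
#'   \item{\code{invariant}}{unchanged,}
#'   \item{\code{length}}{multiplied by c,}
#'   \item{\code{area}}{multiplied by c^2,}
#'   \item{\code{inv_length}}{multiplied by 1/c,}
#'   \item{\code{none}}{no exact scaling law (sway-density measures at a
#'     fixed absolute radius).}
#' }
#' Only the mean positions (indices 1 and 2) respond to a rigid translation.
#'
#' @return A data frame with columns \code{index}, \code{name},
#'   \code{channel}, \code{log_transform}, \code{scaling}.
#' @export
index_catalog <- function() {
  L <- function(index, name, channel, log_transform, scaling) {
    data.frame(index = index, name = name, channel = channel,
               log_transform = log_transform, scaling = scaling,
               stringsAsFactors = FALSE)
  }
  cat_ <- rbind(
    L(1,  "Mean-ML",             "ml",     FALSE, "length"),
    L(2,  "Mean-AP",             "ap",     FALSE, "length"),
    L(3,  "log-Area",            "planar", TRUE,  "area"),
    L(4,  "log-Axis1",           "planar", TRUE,  "length"),
    L(5,  "log-Axis2",           "planar", TRUE,  "length"),
    L(6,  "Angle",               "planar", FALSE, "invariant"),
    L(7,  "Mean-cross-ML",       "ml",     FALSE, "invariant"),
    L(8,  "Mean-cross-AP",       "ap",     FALSE, "invariant"),
    L(9,  "Slope-L-ML",          "ml",     FALSE, "invariant"),
    L(10, "Slope-H-ML",          "ml",     FALSE, "invariant"),
    L(11, "Critical-freq-ML",    "ml",     FALSE, "invariant"),
    L(12, "Slope-L-AP",          "ap",     FALSE, "invariant"),
    L(13, "Slope-H-AP",          "ap",     FALSE, "invariant"),
    L(14, "Critical-freq-AP",    "ap",     FALSE, "invariant"),
    L(15, "Zero-cross-V-ML",     "ml",     FALSE, "invariant"),
    L(16, "Zero-cross-V-AP",     "ap",     FALSE, "invariant"),
    L(17, "log-LNG",             "planar", TRUE,  "length"),
    L(18, "log-LNG/Area",        "planar", TRUE,  "inv_length"),
    L(19, "log-Alpha-ML",        "ml",     TRUE,  "invariant"),
    L(20, "Beta-ML",             "ml",     FALSE, "invariant"),
    L(21, "log-Alpha-AP",        "ap",     TRUE,  "invariant"),
    L(22, "Beta-AP",             "ap",     FALSE, "invariant"),
    L(23, "MT3",                 "planar", FALSE, "none"),
    L(24, "MP3",                 "planar", FALSE, "none"),
    L(25, "MD3",                 "planar", FALSE, "none"),
    L(26, "Mean-MT",             "planar", FALSE, "none"),
    L(27, "log-Slope-MP",        "planar", TRUE,  "none"),
    L(28, "Mean-MD",             "planar", FALSE, "none"),
    L(29, "FD",                  "planar", FALSE, "invariant"),
    L(30, "log-Area-SW",         "planar", TRUE,  "area"),
    L(31, "MFREQ",               "planar", FALSE, "invariant"),
    L(32, "MFREQ-ML",            "ml",     FALSE, "invariant"),
    L(33, "MFREQ-AP",            "ap",     FALSE, "invariant"),
    L(34, "log-Power",           "planar", TRUE,  "area"),
    L(35, "PF50",                "planar", FALSE, "invariant"),
    L(36, "PF95",                "planar", FALSE, "invariant"),
    L(37, "log-Power-ML",        "ml",     TRUE,  "area"),
    L(38, "PF50-ML",             "ml",     FALSE, "invariant"),
    L(39, "PF95-ML",             "ml",     FALSE, "invariant"),
    L(40, "log-Power-AP",        "ap",     TRUE,  "area"),
    L(41, "PF50-AP",             "ap",     FALSE, "invariant"),
    L(42, "PF95-AP",             "ap",     FALSE, "invariant"),
    L(43, "D-short",             "planar", FALSE, "area"),
    L(44, "D-long",              "planar", FALSE, "area"),
    L(45, "Critical-dt-linear",  "planar", FALSE, "invariant"),
    L(46, "Critical-D-linear",   "planar", FALSE, "area"),
    L(47, "D-short-ML",          "ml",     FALSE, "area"),
    L(48, "D-long-ML",           "ml",     FALSE, "area"),
    L(49, "Critical-dt-linear-ML", "ml",   FALSE, "invariant"),
    L(50, "Critical-D-linear-ML", "ml",    FALSE, "area"),
    L(51, "D-short-AP",          "ap",     FALSE, "area"),
    L(52, "D-long-AP",           "ap",     FALSE, "area"),
    L(53, "Critical-dt-linear-AP", "ap",   FALSE, "invariant"),
    L(54, "Critical-D-linear-AP", "ap",    FALSE, "area"),
    L(55, "Slope-short",         "planar", FALSE, "invariant"),
    L(56, "Slope-long",          "planar", FALSE, "invariant"),
    L(57, "Critical-dt-log",     "planar", FALSE, "invariant"),
    L(58, "Critical-D-log",      "planar", FALSE, "area"),
    L(59, "Slope-short-ML",      "ml",     FALSE, "invariant"),
    L(60, "Slope-long-ML",       "ml",     FALSE, "invariant"),
    L(61, "Critical-dt-log-ML",  "ml",     FALSE, "invariant"),
    L(62, "Critical-D-log-ML",   "ml",     FALSE, "area"),
    L(63, "Slope-short-AP",      "ap",     FALSE, "invariant"),
    L(64, "Slope-long-AP",       "ap",     FALSE, "invariant"),
    L(65, "Critical-dt-log-AP",  "ap",     FALSE, "invariant"),
    L(66, "Critical-D-log-AP",   "ap",     FALSE, "area"),
    L(67, "log-RMS",             "planar", TRUE,  "length"),
    L(68, "log-RMS-ML",          "ml",     TRUE,  "length"),
    L(69, "log-RMS-AP",          "ap",     TRUE,  "length"),
    L(70, "log-MV",              "planar", TRUE,  "length"),
    L(71, "log-MV-ML",           "ml",     TRUE,  "length"),
    L(72, "log-MV-AP",           "ap",     TRUE,  "length"),
    L(73, "Flattening",          "planar", FALSE, "invariant")
  )
  cat_$index <- as.integer(cat_$index)
  stopifnot(identical(cat_$index, 1:73))
  cat_
}

#' Index numbers whose raw values are log10-transformed before screening
#' @return Integer vector of index numbers.
#' @export
log_index_set <- function() {
  cat_ <- index_catalog()
  cat_$index[cat_$log_transform]
}

index_name <- function(k) index_catalog()$name[k]
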