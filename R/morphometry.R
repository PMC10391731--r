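#' Ellipsoid lobe volume
#'
#' Standard ellipsoid volume from three caliper diameters:
#' height x width x depth x pi / 6. When the dorsoventral depth was not
#' measured, the transverse diameter (width) is substituted for it, per the
#' assay's measuring convention. Outputs carry the cube of the input unit.
#'
#' @param height,width Longitudinal (pole-to-pole) and transverse
#'   (medial-to-lateral) diameters; strictly positive.
#' @param depth Dorsoventral diameter; `NULL` or `NA` values fall back to
#'   `width`.
#' @return Numeric vector of volumes.
#' @examples
#' ellipsoid_volume(1, 1, 1)       # pi/6
#' ellipsoid_volume(2, 3)          # depth defaults to width: 3*pi
#' @export
ellipsoid_volume <- function(height, width, depth = NULL) {
  if (is.null(depth)) depth <- rep(NA_real_, length(width))
  depth <- ifelse(is.na(depth), width, depth)
  n <- max(length(height), length(width), length(depth))
  height <- rep_len(height, n); width <- rep_len(width, n)
  depth <- rep_len(depth, n)
  if (any(height <= 0 | width <= 0 | depth <= 0, na.rm = TRUE) ||
      any(is.na(height) | is.na(width)))
    stop("all dimensions must be strictly positive", call. = FALSE)
  height * width * depth * pi / 6
}

#' Pooled tumor-burden ratio
#'
#' Tumor area per total lung area across standardized section levels:
#' sum(tumor_area) / sum(total_area), i.e. an area-weighted pooled ratio
#' (per-section ratios are returned as an attribute). Invariant to area
#' unit rescaling.
#'
#' @param tumor_area Numeric vector of per-section tumor areas, or a
#'   data.frame with columns `tumor_area` and `total_area`.
#' @param total_area Numeric vector of per-section total lung areas.
#' @return The pooled ratio in `[0, 1]`, with attribute `per_section`.
#' @examples
#' tumor_burden(c(1, 2, 0), c(10, 10, 10))  # 0.1
#' @export
tumor_burden <- function(tumor_area, total_area = NULL) {
  if (is.data.frame(tumor_area)) {
    total_area <- tumor_area$total_area
    tumor_area <- tumor_area$tumor_area
  }
  if (length(tumor_area) == 0L || length(tumor_area) != length(total_area))
    stop("need matching per-section tumor and total areas", call. = FALSE)
  if (any(total_area < 0) || sum(total_area) <= 0)
    stop("total section area must be positive", call. = FALSE)
  if (any(tumor_area < 0 | tumor_area > total_area))
    stop("tumor area must lie in [0, total area] per section", call. = FALSE)
  ratio <- sum(tumor_area) / sum(total_area)
  attr(ratio, "per_section") <- ifelse(total_area > 0,
                                       tumor_area / total_area, NA_real_)
  ratio
}

#' Per-sample morphometry from measurement tables
#'
#' Consumes a caliper-measurement table (`sample`, `height`, `width`,
#' optional `depth`) and an optional section-area table (`sample`,
#' `tumor_area`, `total_area`) and emits one row per sample with lobe
#' volume and pooled tumor burden.
#'
#' @param measurements Data.frame of lobe diameters.
#' @param areas Optional data.frame of per-section areas.
#' @return Data.frame with `sample`, `volume`, and (when `areas` is given)
#'   `tumor_burden`.
#' @export
morphometry_table <- function(measurements, areas = NULL) {
  stopifnot(all(c("sample", "height", "width") %in% names(measurements)))
  out <- data.frame(
    sample = measurements$sample,
    volume = ellipsoid_volume(measurements$height, measurements$width,
                              measurements$depth %||% NULL),
    stringsAsFactors = FALSE)
  if (!is.null(areas)) {
    tb <- vapply(out$sample, function(s) {
      a <- areas[areas$sample == s, , drop = FALSE]
      if (nrow(a) == 0L) return(NA_real_)
      as.numeric(tumor_burden(a$tumor_area, a$total_area))
    }, numeric(1))
    out$tumor_burden <- unname(tb)
  }
  out
}
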