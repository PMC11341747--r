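## Device catalogue: the Contour product-selection table (five rows,
## selection by aneurysm neck width d_n and maximum width d_a) and a
## representative braided flow-diverter (SVB) size range. The deployed
## braid porosity (60%) and pore density (45, stored as printed) come
## from the manufacturers' deployed-device specifications; the Contour
## rows carry no published porosity and are stored as missing.

#' Load the device catalogue
#'
#' @return list with two data frames, `contour` (product code,
#'   microcatheter inner diameter in inches, nominal diameter, d_n and
#'   d_a selection ranges in mm) and `braided` (SVB-style diameters x
#'   15 mm length, nominal deployed porosity and pore density).
#' @export
deviceCatalogue <- function() {
  path <- system.file("extdata", "device_catalogue.json",
                      package = "aneutreat")
  if (path == "") path <- file.path("inst", "extdata",
                                    "device_catalogue.json")
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  cont <- raw$contour
  cont$dn_min <- vapply(cont$dn_range_mm, `[`, numeric(1), 1)
  cont$dn_max <- vapply(cont$dn_range_mm, `[`, numeric(1), 2)
  cont$da_min <- vapply(cont$da_range_mm, `[`, numeric(1), 1)
  cont$da_max <- vapply(cont$da_range_mm, `[`, numeric(1), 2)
  cont$dn_range_mm <- cont$da_range_mm <- NULL
  br <- raw$braided
  for (col in c("nominal_diameter_mm", "length_mm", "nominal_porosity",
                "nominal_pore_density_per_mm")) {
    if (col %in% names(cont)) cont[[col]] <- as.numeric(cont[[col]])
    if (col %in% names(br)) br[[col]] <- as.numeric(br[[col]])
  }
  list(contour = cont, braided = br)
}

#' Select a Contour device from aneurysm measures
#'
#' Containment of the neck width `d_n` in a product's d_n range is the
#' hard criterion; containment of `d_a` is advisory (preferred among
#' qualifying rows, a warning when the selected row does not contain it,
#' never an error). Ties are broken towards the smallest nominal
#' diameter.
#'
#' @param d_n neck width (mm). @param d_a maximum aneurysm width (mm).
#' @param catalogue catalogue as returned by [deviceCatalogue()].
#' @return a one-row `deviceSpec` (list) for the selected product.
#' @export
selectContour <- function(d_n, d_a, catalogue = deviceCatalogue()) {
  stopifnot(is.finite(d_n), is.finite(d_a), d_n > 0, d_a > 0)
  ct <- catalogue$contour
  hit <- which(ct$dn_min <= d_n & d_n <= ct$dn_max)
  if (length(hit) == 0) {
    nearest <- order(pmax(ct$dn_min - d_n, d_n - ct$dn_max))[1:2]
    stop("sizing error: no catalogued Contour device covers d_n = ", d_n,
         " mm (nearest rows: ",
         paste(ct$product_code[nearest], collapse = ", "), ")")
  }
  if (length(hit) > 1) {
    daok <- hit[ct$da_min[hit] <= d_a & d_a <= ct$da_max[hit]]
    if (length(daok) > 0) hit <- daok
    hit <- hit[which.min(ct$nominal_diameter_mm[hit])]
  }
  row <- lapply(ct, `[`, hit)
  if (!(row$da_min <= d_a && d_a <= row$da_max))
    warning("d_a = ", d_a, " mm lies outside the advisory range [",
            row$da_min, ", ", row$da_max, "] mm of ", row$product_code)
  structure(row, class = "deviceSpec")
}

#' Select a braided flow-diverter size for a target vessel
#'
#' Chooses the smallest catalogued nominal diameter not below the target
#' vessel diameter (standard slight oversizing for wall apposition).
#'
#' @param vessel_diameter diameter (mm) of the vessel the stent lands in.
#' @param catalogue catalogue as returned by [deviceCatalogue()].
#' @return a one-row `deviceSpec`.
#' @export
selectBraided <- function(vessel_diameter, catalogue = deviceCatalogue()) {
  stopifnot(is.finite(vessel_diameter), vessel_diameter > 0)
  br <- catalogue$braided
  hit <- which(br$nominal_diameter_mm >= vessel_diameter)
  if (length(hit) == 0)
    stop("sizing error: vessel diameter ", vessel_diameter,
         " mm exceeds the largest catalogued braided device (",
         max(br$nominal_diameter_mm), " mm)")
  hit <- hit[which.min(br$nominal_diameter_mm[hit])]
  structure(lapply(br, `[`, hit), class = "deviceSpec")
}

#' @export
print.deviceSpec <- function(x, ...) {
  cat("deviceSpec:", x$product_code, "(", x$family, ")\n")
  cat("  nominal diameter:", x$nominal_diameter_mm, "mm")
  if (!is.null(x$length_mm) && !is.na(x$length_mm))
    cat(" x", x$length_mm, "mm")
  cat("; microcatheter", x$microcatheter_id_in, "in\n")
  if (!is.null(x$dn_min) && length(x$dn_min))
    cat("  d_n range [", x$dn_min, ",", x$dn_max, "] mm; d_a range [",
        x$da_min, ",", x$da_max, "] mm\n")
  invisible(x)
}
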