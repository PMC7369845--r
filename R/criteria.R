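# Geometric criteria for the six interaction classes plus the docking-stage
# proton-heteroatom contact. All distance bounds are maxima, all angle
# bounds minima (ranges for edge-to-face), and every threshold is inclusive:
# the criteria are cutoffs, not targets.

#' Geometric interaction criteria
#'
#' Defaults:
#' \itemize{
#'   \item docking contact: proton...heteroatom distance <= 3.2 A;
#'   \item H-bond: donor-acceptor distance <= 2.5 A, donor angle
#'     (D-H...A, at H) >= 120 deg, acceptor angle (H...A-X, at A) >= 90 deg;
#'   \item water bridge: relaxed H-bond on both sides of one water --
#'     2.8 A / 110 deg / 90 deg;
#'   \item pi-cation: ring centroid to charge site <= 4.5 A;
#'   \item hydrophobic: apolar carbon/sulfur pair <= 3.6 A;
#'   \item ionic: opposite charge sites <= 3.7 A (suppressed by an H-bond
#'     between the same groups);
#'   \item pi-pi: face-to-face when centroids <= 4.4 A and interplanar angle
#'     <= 30 deg; edge-to-face when centroids <= 5.5 A and angle in
#'     60-90 deg (normals folded to the unsigned range). The centroid
#'     cutoffs are calibrated so observed parallel stacks at 3.4 A and
#'     T-shaped pairs at 3.7 A are detected while a 4.7 A parallel
#'     separation is not.
#' }
#'
#' @param docking_contact_max,hbond_da_max,wb_da_max,pication_max,hydrophobic_max,ionic_max,pipi_f2f_centroid_max,pipi_e2f_centroid_max distances, A.
#' @param hbond_donor_angle_min,hbond_acceptor_angle_min,wb_donor_angle_min,wb_acceptor_angle_min,pipi_f2f_angle_max angles, degrees.
#' @param pipi_e2f_angle_range numeric length-2, degrees (unsigned fold maps
#'   it to \[60, 90\]).
#' @return list of class `geometric_criteria`.
#' @export
geometric_criteria <- function(docking_contact_max = 3.2,
                               hbond_da_max = 2.5,
                               hbond_donor_angle_min = 120,
                               hbond_acceptor_angle_min = 90,
                               wb_da_max = 2.8,
                               wb_donor_angle_min = 110,
                               wb_acceptor_angle_min = 90,
                               pication_max = 4.5,
                               hydrophobic_max = 3.6,
                               ionic_max = 3.7,
                               pipi_f2f_centroid_max = 4.4,
                               pipi_e2f_centroid_max = 5.5,
                               pipi_f2f_angle_max = 30,
                               pipi_e2f_angle_range = c(60, 120)) {
  cr <- list(docking_contact_max = docking_contact_max,
             hbond_da_max = hbond_da_max,
             hbond_donor_angle_min = hbond_donor_angle_min,
             hbond_acceptor_angle_min = hbond_acceptor_angle_min,
             wb_da_max = wb_da_max,
             wb_donor_angle_min = wb_donor_angle_min,
             wb_acceptor_angle_min = wb_acceptor_angle_min,
             pication_max = pication_max,
             hydrophobic_max = hydrophobic_max,
             ionic_max = ionic_max,
             pipi_f2f_centroid_max = pipi_f2f_centroid_max,
             pipi_e2f_centroid_max = pipi_e2f_centroid_max,
             pipi_f2f_angle_max = pipi_f2f_angle_max,
             pipi_e2f_angle_range = pipi_e2f_angle_range)
  dists <- unlist(cr[grepl("max$", names(cr)) & !grepl("angle", names(cr))])
  if (any(dists <= 0)) stop("distance thresholds must be positive")
  angs <- c(cr$hbond_donor_angle_min, cr$hbond_acceptor_angle_min,
            cr$wb_donor_angle_min, cr$wb_acceptor_angle_min,
            cr$pipi_f2f_angle_max, cr$pipi_e2f_angle_range)
  if (any(angs < 0 | angs > 180)) stop("angle bounds must lie in [0, 180]")
  structure(cr, class = "geometric_criteria")
}

#' Load criteria overrides from a JSON config file
#'
#' The file holds a single JSON object whose keys are
#' \code{\link{geometric_criteria}} argument names; unspecified thresholds
#' keep their defaults.
#'
#' @param path JSON file.
#' @return a `geometric_criteria` list.
#' @export
read_criteria <- function(path) {
  ov <- jsonlite::read_json(path, simplifyVector = TRUE)
  bad <- setdiff(names(ov), names(formals(geometric_criteria)))
  if (length(bad)) stop("unknown criteria name(s): ", paste(bad, collapse = ", "))
  do.call(geometric_criteria, ov)
}
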