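#' Expected neurons within an electrode's sensitivity volume
#'
#' Closed-form count of neurons inside the half-spherical volume in front of
#' a polytrode electrode site: `density * (2/3) * pi * (radius_um / 1000)^3`.
#' With cortical density estimates of 40,000-60,000 neurons/mm^3 and a 50-um
#' sensitivity radius, each site is expected to be sensitive to roughly 10-15
#' neurons.
#'
#' @param density_per_mm3 neuronal density, neurons per cubic millimetre.
#' @param radius_um sensitivity radius, micrometres.
#' @return list: `expected` (unrounded count), `rounded` (nearest integer),
#'   `volume_mm3`, plus the inputs.
#' @examples
#' expected_neurons_per_site(40000, 50)$rounded  # 10
#' @export
expected_neurons_per_site <- function(density_per_mm3, radius_um) {
  if (density_per_mm3 <= 0) stop("density_per_mm3 must be positive")
  if (radius_um < 0) stop("radius_um must be non-negative")
  vol <- (2 / 3) * pi * (radius_um / 1000)^3
  expected <- density_per_mm3 * vol
  list(expected = expected, rounded = round(expected), volume_mm3 = vol,
       density_per_mm3 = density_per_mm3, radius_um = radius_um)
}
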