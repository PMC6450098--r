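#' Triangulation number of an icosahedral lattice
#'
#' Computes the quasi-equivalence triangulation number
#' \eqn{T = h^2 + hk + k^2} from the lattice walk indices \eqn{(h, k)}.
#' For the medusavirus capsid the indices are \eqn{(h = 7, k = 12)},
#' giving \eqn{T = 277}.
#'
#' @param h,k Non-negative integer lattice indices; not both zero.
#' @return Integer triangulation number.
#' @examples
#' t_number(7, 12) # 277
#' t_number(1, 0)  # 1
#' @export
t_number <- function(h, k) {
  stopifnot(length(h) == 1, length(k) == 1, is.finite(h), is.finite(k))
  if (h < 0 || k < 0 || h != round(h) || k != round(k)) {
    rlang::abort("`h` and `k` must be non-negative integers.")
  }
  if (h == 0 && k == 0) {
    rlang::abort("at least one of `h`, `k` must be positive.")
  }
  as.integer(h^2 + h * k + k^2)
}

#' Find lattice indices for a given triangulation number
#'
#' Brute-force search over \eqn{0 \le h \le k \le max_index} for the
#' index pairs satisfying \eqn{h^2 + hk + k^2 = T}. Returns the smallest
#' pair (by h, then k) by default.
#'
#' @param t Target triangulation number (positive integer).
#' @param max_index Upper bound of the search (default 50).
#' @param all If `TRUE`, return every `(h <= k)` solution.
#' @return A tibble with columns `h`, `k`, `t`; zero rows if `t` is not
#'   representable within the search bound.
#' @examples
#' hk_for_t(277) # h = 7, k = 12
#' hk_for_t(304) # h = 8, k = 12 (the Melbournevirus capsid)
#' @export
hk_for_t <- function(t, max_index = 50, all = FALSE) {
  stopifnot(length(t) == 1, t >= 1, t == round(t))
  grid <- tidyr::expand_grid(h = 0:max_index, k = 0:max_index) |>
    dplyr::filter(.data$h <= .data$k, .data$h + .data$k >= 1) |>
    dplyr::mutate(t = .data$h^2 + .data$h * .data$k + .data$k^2) |>
    dplyr::filter(.data$t == !!t) |>
    dplyr::arrange(.data$h, .data$k)
  if (!all && nrow(grid) > 0) grid <- grid[1, ]
  grid
}

#' Capsomer census of a T-number capsid
#'
#' A closed icosahedral lattice has exactly 12 pentamers (Euler's
#' relation) and \eqn{10(T - 1)} hexamers, for \eqn{10T + 2} capsomers
#' in total.
#'
#' @param t Triangulation number (positive integer).
#' @return One-row tibble with `t`, `pentamers`, `hexamers`, `total`.
#' @examples
#' capsomer_census(277)
#' @export
capsomer_census <- function(t) {
  stopifnot(length(t) == 1, t >= 1, t == round(t))
  tibble::tibble(
    t = as.integer(t),
    pentamers = 12L,
    hexamers = as.integer(10 * (t - 1)),
    total = as.integer(10 * t + 2)
  )
}

#' Mean capsomer spacing on an icosahedral capsid
#'
#' Under the `edge_over_sqrtT` model the icosahedron edge is
#' \eqn{a = 4R/\sqrt{10 + 2\sqrt 5}} for circumradius \eqn{R} (the
#' vertex-touching sphere), and the pentamer-to-pentamer lattice path
#' along an edge contains \eqn{\sqrt T} inter-capsomer spacings, so the
#' spacing is \eqn{d = a/\sqrt T}.
#'
#' @param t Triangulation number.
#' @param capsid_diameter Vertex-circumscribed capsid diameter in nm.
#' @param model Geometric model; only `"edge_over_sqrtT"` is defined.
#' @return One-row tibble with `t`, `capsid_diameter_nm`, `edge_nm`,
#'   `spacing_nm`, `model`.
#' @examples
#' capsomer_spacing(277, 232) # ~7.33 nm
#' @export
capsomer_spacing <- function(t, capsid_diameter, model = "edge_over_sqrtT") {
  stopifnot(length(t) == 1, t >= 1, capsid_diameter > 0)
  model <- match.arg(model)
  r <- capsid_diameter / 2
  edge <- 4 * r / sqrt(10 + 2 * sqrt(5))
  tibble::tibble(
    t = as.integer(t),
    capsid_diameter_nm = capsid_diameter,
    edge_nm = edge,
    spacing_nm = edge / sqrt(t),
    model = model
  )
}

#' Total virion diameter including surface spikes
#'
#' Spikes extend radially from the capsid surface on both sides of any
#' diameter, so the total particle size is
#' `capsid_diameter + 2 * spike_length`.
#'
#' @param capsid_diameter Capsid diameter in nm (spikes excluded).
#' @param spike_length Spike length in nm.
#' @return Total diameter in nm.
#' @examples
#' total_diameter(232, 14) # 260
#' @export
total_diameter <- function(capsid_diameter, spike_length) {
  stopifnot(capsid_diameter > 0, spike_length >= 0)
  capsid_diameter + 2 * spike_length
}

#' Full capsid geometry report
#'
#' Combines the lattice arithmetic into a single model object: the
#' T number, capsomer census (which under the one-spike-per-capsomer
#' assumption is also the spike count), mean capsomer spacing, and the
#' virion dimension accounting. The published spike count for the
#' medusavirus capsid (2,660) differs from the lattice total
#' \eqn{10T + 2 = 2772}; the published value is echoed alongside, never
#' silently adopted.
#'
#' @param h,k Lattice indices.
#' @param capsid_diameter Capsid diameter in nm, excluding spikes.
#' @param spike_length Spike length in nm.
#' @param published_spikes Optional externally reported spike count to
#'   echo in the report (`NA` to omit).
#' @return An object of class `capsid_model` (a one-row tibble).
#' @examples
#' capsid_report(7, 12, capsid_diameter = 232, spike_length = 14)
#' @export
capsid_report <- function(h, k, capsid_diameter, spike_length,
                          published_spikes = NA_integer_) {
  t <- t_number(h, k)
  census <- capsomer_census(t)
  spacing <- capsomer_spacing(t, capsid_diameter)
  out <- tibble::tibble(
    h = as.integer(h), k = as.integer(k), t = t,
    pentamers = census$pentamers,
    hexamers = census$hexamers,
    capsomers_total = census$total,
    spikes_lattice = census$total,
    spikes_published = as.integer(published_spikes),
    capsid_diameter_nm = capsid_diameter,
    spike_length_nm = spike_length,
    total_diameter_nm = total_diameter(capsid_diameter, spike_length),
    spacing_nm = spacing$spacing_nm,
    spacing_model = spacing$model
  )
  class(out) <- c("capsid_model", class(out))
  out
}

#' @export
glance.capsid_model <- function(x, ...) {
  tibble::as_tibble(x)[, c("t", "capsomers_total", "total_diameter_nm",
                           "spacing_nm")]
}
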