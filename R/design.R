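#' Discrete tACS search space
#'
#' The hardware lattice over which stimulation parameters are selected:
#' frequency 5–50 Hz in 1 Hz steps and current 0.1–1.6 mA peak-to-peak in
#' 0.1 mA steps. During the burn-in phase only active currents are assigned;
#' in the optimization phase 0 mA (sham) is added, giving 46 x 16 = 736 and
#' 46 x 17 = 782 combinations respectively.
#'
#' Unit-cube normalization always uses the fixed physical bounds
#' frequency in \[5, 50\] Hz and current in \[0, 1.6\] mA, in both phases, so
#' that a given (frequency, current) pair has one location in kernel space
#' throughout a study.
#'
#' @param phase `"optimization"` (default) or `"burn_in"`.
#' @param baseline_bounds numeric length-2: the raw drift-rate range mapped
#'   to the unit interval for the personalization covariate. The default
#'   \[0, 0.2\] brackets typical baseline drifts (cohort mean near 0.055).
#' @return an object of class `persbo_space`.
#' @export
search_space <- function(phase = c("optimization", "burn_in"),
                         baseline_bounds = c(0, 0.2)) {
  phase <- match.arg(phase)
  stopifnot(length(baseline_bounds) == 2L, diff(baseline_bounds) > 0)
  currents <- round(seq(0.1, 1.6, by = 0.1), 1)
  if (phase == "optimization") currents <- c(0, currents)
  structure(
    list(
      phase = phase,
      frequencies = 5:50,
      currents = currents,
      freq_bounds = c(5, 50),
      current_bounds = c(0, 1.6),
      baseline_bounds = baseline_bounds
    ),
    class = "persbo_space"
  )
}

#' @export
print.persbo_space <- function(x, ...) {
  cat(sprintf("<persbo_space: %s phase, %d frequencies x %d currents = %d combinations>\n",
              x$phase, length(x$frequencies), length(x$currents),
              length(x$frequencies) * length(x$currents)))
  invisible(x)
}

#' Enumerate the stimulation lattice
#'
#' @param space a [search_space()].
#' @return tibble of all `frequency` x `current` combinations in a
#'   deterministic order (frequency-major, current ascending).
#' @export
stim_grid <- function(space) {
  stopifnot(inherits(space, "persbo_space"))
  tidyr::expand_grid(frequency = space$frequencies,
                     current = sort(space$currents))
}

#' Map physical parameters (and baseline) to the unit cube
#'
#' Affine min-max maps: frequency over \[5, 50\], current over \[0, 1.6\],
#' and the raw baseline drift over `space$baseline_bounds`. Baseline values
#' outside their bounds are clipped with a warning.
#'
#' @param data data frame with columns `frequency` and `current`, and
#'   optionally `p_raw`.
#' @param space a [search_space()].
#' @return `data` with unit-scale columns `x1` (frequency), `x2` (current)
#'   and, when `p_raw` is present, `p` appended.
#' @export
normalize_coords <- function(data, space) {
  stopifnot(inherits(space, "persbo_space"),
            all(c("frequency", "current") %in% names(data)))
  fb <- space$freq_bounds; cb <- space$current_bounds
  out <- mutate(as_tibble(data),
                x1 = (.data$frequency - fb[1]) / diff(fb),
                x2 = (.data$current - cb[1]) / diff(cb))
  if ("p_raw" %in% names(data)) {
    bb <- space$baseline_bounds
    p <- (data$p_raw - bb[1]) / diff(bb)
    if (any(p < 0 | p > 1, na.rm = TRUE)) {
      warn_persbo("baseline ability outside configured bounds; clipping to [0, 1].",
                  "baseline_clipped")
      p <- pmin(pmax(p, 0), 1)
    }
    out$p <- p
  }
  out
}

#' Invert the unit-cube map back to physical parameters
#'
#' @param coords data frame with unit-scale columns `x1`, `x2`.
#' @param space a [search_space()].
#' @param snap snap results to the nearest lattice member (default), making
#'   `denormalize_coords(normalize_coords(g)) == g` exact on the grid.
#' @return `coords` with `frequency` and `current` columns appended/replaced.
#' @export
denormalize_coords <- function(coords, space, snap = TRUE) {
  stopifnot(inherits(space, "persbo_space"),
            all(c("x1", "x2") %in% names(coords)))
  fb <- space$freq_bounds; cb <- space$current_bounds
  freq <- coords$x1 * diff(fb) + fb[1]
  curr <- coords$x2 * diff(cb) + cb[1]
  if (snap) {
    freq <- vapply(freq, function(f) space$frequencies[which.min(abs(space$frequencies - f))], 0)
    curr <- vapply(curr, function(c0) space$currents[which.min(abs(space$currents - c0))], 0)
  }
  mutate(as_tibble(coords), frequency = freq, current = curr)
}

#' Double-blind parameter codebook
#'
#' A seeded pseudo-random bijection between grid combinations and opaque
#' 3-digit integer codes, so that neither experimenter nor subject can read
#' current or frequency (sham 0 mA included) off the code handed to the
#' stimulation software.
#'
#' @param space a [search_space()]; the codebook covers its full grid.
#' @param seed integer seed.
#' @return tibble with columns `code`, `frequency`, `current`; attributes
#'   `seed` and `phase`.
#' @export
make_codebook <- function(space, seed) {
  grid <- stim_grid(space)
  codes <- withr::with_seed(seed, sample(100:999, nrow(grid)))
  out <- mutate(grid, code = codes, .before = 1)
  attr(out, "seed") <- as.integer(seed)
  attr(out, "phase") <- space$phase
  out
}

#' Encode / decode blinded stimulation codes
#'
#' @param params data frame with `frequency`, `current` rows on the grid.
#' @param codebook a codebook from [make_codebook()].
#' @return `encode_params()`: integer codes; `decode_code()`: tibble of
#'   `frequency`, `current`.
#' @export
encode_params <- function(params, codebook) {
  key <- paste(params$frequency, params$current)
  ref <- paste(codebook$frequency, codebook$current)
  i <- match(key, ref)
  if (anyNA(i)) abort_persbo("parameters not on the codebook grid.", "lookup_error")
  codebook$code[i]
}

#' @rdname encode_params
#' @param code integer code(s) to decode.
#' @export
decode_code <- function(code, codebook) {
  i <- match(code, codebook$code)
  if (anyNA(i)) abort_persbo("unknown stimulation code.", "lookup_error")
  codebook[i, c("frequency", "current")]
}

#' @rdname encode_params
#' @param path JSON file path.
#' @export
write_codebook <- function(codebook, path) {
  entries <- setNames(
    purrr::map2(codebook$frequency, codebook$current,
                ~ list(frequency = .x, current = .y)),
    as.character(codebook$code)
  )
  jsonlite::write_json(
    list(seed = attr(codebook, "seed"), phase = attr(codebook, "phase"),
         codes = entries),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname encode_params
#' @export
read_codebook <- function(path) {
  obj <- jsonlite::read_json(path)
  out <- tibble(
    code = as.integer(names(obj$codes)),
    frequency = purrr::map_dbl(obj$codes, "frequency"),
    current = purrr::map_dbl(obj$codes, "current")
  )
  attr(out, "seed") <- obj$seed
  attr(out, "phase") <- obj$phase
  out
}
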