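## Stimulus protocols. A protocol is a small description object; for
## integration it is compiled into contiguous time segments over which the
## external drive is smooth (constant injected current and bath composition,
## linear indentation ramp, fixed Piezo2 phase flag). Segment boundaries are
## solver restart points.

.new_protocol <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "merkel_protocol")
}

#' Stimulus protocols
#'
#' Constructors for the four experiment drives plus the null protocol.
#' Times are seconds of simulated time.
#'
#' * `protocol_none()`: no stimulus (rest).
#' * `protocol_current_pulse(amplitude_pA, onset, duration)`: rectangular
#'   injected-current pulse; enters the membrane-potential equation only.
#' * `protocol_high_k(delta_K, delta_Na, onset, duration)`: bath swap,
#'   raising external K+ by `delta_K` and changing Na+ by `delta_Na`
#'   (both mM; the classic high-K+ solution is `+130 / -130`).
#' * `protocol_hypotonic(remove_mannitol, onset, duration)`: removes
#'   `remove_mannitol` mM of impermeant external osmolyte (the baseline bath
#'   must contain it); lowers the external osmolarity, the cell swells and
#'   cortex stress rises. The Piezo2 phase flag is `loading` while the
#'   shock is applied.
#' * `protocol_compression(depth_um, speed_um_per_ms, onset, hold, release)`:
#'   indentation ramp at constant speed to `depth_um`, held for `hold`
#'   seconds, then (optionally) released at the same speed. The phase flag
#'   is `loading` from ramp onset until release, `unloading` afterwards.
#'
#' @param amplitude_pA Injected current (pA), positive depolarising.
#' @param onset Stimulus onset (s).
#' @param duration Stimulus duration (s); `Inf` = until the horizon.
#' @param delta_K,delta_Na Bath concentration changes (mM).
#' @param remove_mannitol External osmolyte removed (mM).
#' @param depth_um Indentation depth (um).
#' @param speed_um_per_ms Ramp speed (um/ms).
#' @param hold Hold time at depth (s); `Inf` = held to the horizon.
#' @param release If `FALSE` the indenter is never released.
#' @return A `"merkel_protocol"` object.
#' @name protocols
NULL

#' @rdname protocols
#' @export
protocol_none <- function() .new_protocol("none")

#' @rdname protocols
#' @export
protocol_current_pulse <- function(amplitude_pA, onset = 0.01, duration = 0.2) {
  stopifnot(onset >= 0, duration > 0)
  .new_protocol("current_pulse", I_app = amplitude_pA * 1e-12,
                onset = onset, duration = duration)
}

#' @rdname protocols
#' @export
protocol_high_k <- function(delta_K = 130, delta_Na = -130, onset = 0.5,
                            duration = Inf) {
  stopifnot(onset >= 0, duration > 0)
  .new_protocol("high_K", delta_K = delta_K, delta_Na = delta_Na,
                onset = onset, duration = duration)
}

#' @rdname protocols
#' @export
protocol_hypotonic <- function(remove_mannitol = 30, onset = 0.5,
                               duration = Inf) {
  stopifnot(onset >= 0, duration > 0)
  .new_protocol("hypotonic", remove_mannitol = remove_mannitol,
                onset = onset, duration = duration)
}

#' @rdname protocols
#' @export
protocol_compression <- function(depth_um, speed_um_per_ms = 1, onset = 0.05,
                                 hold = Inf, release = TRUE) {
  stopifnot(depth_um > 0, speed_um_per_ms > 0, onset >= 0, hold > 0)
  .new_protocol("compression", depth = depth_um * 1e-6,
                speed = speed_um_per_ms * 1e-3, onset = onset, hold = hold,
                release = isTRUE(release))
}

#' @export
print.merkel_protocol <- function(x, ...) {
  cat("Merkel-cell stimulus protocol: ", x$kind, "\n", sep = "")
  for (nm in setdiff(names(x), "kind")) cat("  ", nm, " = ", format(x[[nm]]), "\n", sep = "")
  invisible(x)
}

## Compile a protocol into smooth segments. Each segment is a list:
##   t0, t1, I_app (A), ext (list Na/K/Cl/Ca/mannitol, mol/m^3),
##   d0 (depth at t0, m), d_rate (m/s), phase ("loading"/"unloading").
protocol_segments <- function(protocol, horizon, external) {
  base <- external
  seg <- function(t0, t1, I_app = 0, ext = base, d0 = 0, d_rate = 0,
                  phase = "unloading") {
    list(t0 = t0, t1 = t1, I_app = I_app, ext = ext, d0 = d0,
         d_rate = d_rate, phase = phase)
  }
  k <- protocol$kind
  if (k == "none") return(list(seg(0, horizon)))
  on <- min(protocol$onset, horizon)
  if (k == "current_pulse") {
    off <- min(on + protocol$duration, horizon)
    segs <- list()
    if (on > 0) segs <- c(segs, list(seg(0, on)))
    if (off > on) segs <- c(segs, list(seg(on, off, I_app = protocol$I_app)))
    if (horizon > off) segs <- c(segs, list(seg(off, horizon)))
    return(segs)
  }
  if (k == "high_K") {
    off <- min(on + protocol$duration, horizon)
    ext <- base
    ext$K <- ext$K + protocol$delta_K
    ext$Na <- ext$Na + protocol$delta_Na
    if (ext$K <= 0 || ext$Na <= 0) stop("high-K swap drives a bath concentration non-positive")
    segs <- list()
    if (on > 0) segs <- c(segs, list(seg(0, on)))
    if (off > on) segs <- c(segs, list(seg(on, off, ext = ext)))
    if (horizon > off) segs <- c(segs, list(seg(off, horizon)))
    return(segs)
  }
  if (k == "hypotonic") {
    off <- min(on + protocol$duration, horizon)
    ext <- base
    ext$mannitol <- ext$mannitol - protocol$remove_mannitol
    if (ext$mannitol < 0) {
      stop("hypotonic protocol removes more mannitol than the baseline bath contains")
    }
    segs <- list()
    if (on > 0) segs <- c(segs, list(seg(0, on)))
    if (off > on) segs <- c(segs, list(seg(on, off, ext = ext, phase = "loading")))
    if (horizon > off) segs <- c(segs, list(seg(off, horizon)))
    return(segs)
  }
  if (k == "compression") {
    ramp <- protocol$depth / protocol$speed
    t_top <- on + ramp
    t_rel <- if (is.finite(protocol$hold)) t_top + protocol$hold else Inf
    segs <- list()
    if (on > 0) segs <- c(segs, list(seg(0, on)))
    if (horizon > on) {
      segs <- c(segs, list(seg(on, min(t_top, horizon), d0 = 0,
                               d_rate = protocol$speed, phase = "loading")))
    }
    if (horizon > t_top) {
      segs <- c(segs, list(seg(t_top, min(t_rel, horizon), d0 = protocol$depth,
                               phase = "loading")))
    }
    if (is.finite(t_rel) && horizon > t_rel && protocol$release) {
      t_down <- t_rel + ramp
      segs <- c(segs, list(seg(t_rel, min(t_down, horizon), d0 = protocol$depth,
                               d_rate = -protocol$speed, phase = "unloading")))
      if (horizon > t_down) segs <- c(segs, list(seg(t_down, horizon)))
    } else if (is.finite(t_rel) && horizon > t_rel) {
      segs <- c(segs, list(seg(t_rel, horizon, d0 = protocol$depth,
                               phase = "loading")))
    }
    return(segs)
  }
  stop("unknown protocol kind '", k, "'")
}
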