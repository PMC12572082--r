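# random admissible parameter draws used by the property-style tests;
# w/L stays inside the empirical band [0, 0.2] so no admissibility warnings
rand_dims <- function() {
  L <- stats::runif(1, 30, 80)
  B <- L * stats::runif(1, 0.55, 0.85)
  w <- L * stats::runif(1, 0.005, 0.2)
  egg_dims(L, B, w)
}

rand_x <- function(dims) stats::runif(1, -dims$L / 2, dims$L / 2)

rel_err <- function(a, b) abs(a - b) / pmax(abs(a), abs(b), 1e-300)

# a realistic ovoid reference egg reused across tests (chicken-like scale)
ref_egg <- function() egg_dims(L = 398, B = 298, w = 20)

# an egg_measure built from known (not re-measured) parameters, the
# measure-once workflow in which every variant consumes the same values
known_measure <- function(dims, B0 = NULL, r = NULL, R = NULL) {
  structure(list(dims = dims, B0 = B0, r = r, R = R, units = "px",
                 scale = NULL, provenance = "known parameters"),
            class = "egg_measure")
}
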