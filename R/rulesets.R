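#' Construct a behavioral rule set
#'
#' A rule set bundles every parameter that governs cell behavior on the
#' scaffold: the attachment threshold, the substrate coupling factor, the
#' per-cell substrate deposit, the lifespan (`T_life`) and proliferation
#' -delay (`T_prol`) draw specifications for initial engrafters and for
#' offspring, and the crowding limit for proliferation targets. Two named
#' rule sets ship with the package ([hypothesis1()], [hypothesis2()]); this
#' constructor exists for variants and parameter perturbations.
#'
#' A draw specification is either `uniform_spec(lo, hi)` (an integer drawn
#' uniformly from the inclusive integer lattice of `[lo, hi]` time steps) or
#' `coupled_spec(base, sign, noise_lo, noise_hi)`, an environment-coupled
#' value `round(scale * (base + sign * c_patch / c_envfactor)) + n` with `n`
#' uniform on the integer lattice of `[noise_lo, noise_hi]`. Coupled values
#' are floored at 1 so that a negative deterministic part cannot produce a
#' cell that never dies or never proliferates.
#'
#' @param name Label of the rule set.
#' @param n_crit Attachment threshold on the 0-100 scale; a uniform draw
#'   above it engrafts a motile cell (5 gives 95% attachment per attempt).
#' @param c_envfactor Divisor coupling substrate concentration to the
#'   offspring formulas (default 1.9).
#' @param c_amount Substrate deposited at engraftment / decayed at death.
#' @param init_life,init_prol Length-2 numeric intervals (time steps) for
#'   initial engrafters.
#' @param off_life,off_prol Draw specifications for offspring cells; exactly
#'   one of the two should be environment-coupled.
#' @param max_target_neighbors A proliferation target patch may have at most
#'   this many occupied neighbors (default 6).
#' @return An object of class `ruleset`.
#' @export
new_ruleset <- function(name, n_crit = 5, c_envfactor = 1.9, c_amount = 1,
                        init_life, init_prol, off_life, off_prol,
                        max_target_neighbors = 6) {
  check_interval <- function(iv, what) {
    if (!is.numeric(iv) || length(iv) != 2 || iv[1] > iv[2] || iv[1] < 0) {
      abort(sprintf("%s must be a numeric interval c(lo, hi) with 0 <= lo <= hi", what))
    }
  }
  check_interval(init_life, "init_life")
  check_interval(init_prol, "init_prol")
  for (s in list(off_life, off_prol)) {
    stopifnot(is.list(s), s$kind %in% c("uniform", "coupled"))
    check_interval(c(s$lo, s$hi), "draw spec interval")
  }
  structure(
    list(
      name = name, n_crit = n_crit, c_envfactor = c_envfactor,
      c_amount = c_amount, init_life = init_life, init_prol = init_prol,
      off_life = off_life, off_prol = off_prol,
      max_target_neighbors = max_target_neighbors
    ),
    class = "ruleset"
  )
}

#' @rdname new_ruleset
#' @param lo,hi Inclusive interval endpoints, time steps.
#' @export
uniform_spec <- function(lo, hi) {
  list(kind = "uniform", lo = lo, hi = hi, base = 0, sign = 0, scale = 1)
}

#' @rdname new_ruleset
#' @param base,sign Deterministic part `base + sign * c_patch / c_envfactor`.
#' @param noise_lo,noise_hi Interval of the additive uniform integer noise.
#' @param scale Multiplier on the deterministic part (used by parameter
#'   perturbations; default 1).
#' @export
coupled_spec <- function(base, sign, noise_lo, noise_hi, scale = 1) {
  list(kind = "coupled", lo = noise_lo, hi = noise_hi, base = base,
       sign = sign, scale = scale)
}

#' Shipped rule sets: short-lived, substrate-seeking proliferation (1) vs
#' long-lived, substrate-dependent survival (2)
#'
#' Under Hypothesis 1, initial engrafters draw `T_life ~ U[0, 36]` and
#' `T_prol ~ U[33, 87]`; offspring draw `T_life ~ U[0, 18]` and an
#' environment-coupled `T_prol = (33 - c_patch/1.9) + U[0, 54]`, so cells
#' proliferate sooner where substrate is abundant. Under Hypothesis 2,
#' initial draws are `T_life ~ U[0, 45]`, `T_prol ~ U[41, 103]`; offspring
#' draw an environment-coupled `T_life = c_patch/1.9 + U[0, 45]` and
#' `T_prol ~ U[41, 103]`, so cells survive longer where substrate is
#' abundant. Everything else (attachment threshold 5, coupling factor 1.9,
#' deposit 1, crowding limit 6) is shared.
#'
#' @return A `ruleset` object.
#' @export
#' @examples
#' hypothesis1()$init_life
#' hypothesis2()$off_life$kind
hypothesis1 <- function() {
  new_ruleset(
    name = "hypothesis1",
    init_life = c(0, 36), init_prol = c(33, 87),
    off_life = uniform_spec(0, 18),
    off_prol = coupled_spec(base = 33, sign = -1, noise_lo = 0, noise_hi = 54)
  )
}

#' @rdname hypothesis1
#' @export
hypothesis2 <- function() {
  new_ruleset(
    name = "hypothesis2",
    init_life = c(0, 45), init_prol = c(41, 103),
    off_life = coupled_spec(base = 0, sign = 1, noise_lo = 0, noise_hi = 45),
    off_prol = uniform_spec(41, 103)
  )
}

#' @export
print.ruleset <- function(x, ...) {
  fmt_spec <- function(s) {
    if (s$kind == "uniform") {
      sprintf("uniform [%g, %g]", s$lo, s$hi)
    } else {
      sprintf(
        "%s(%g %s c/%g) + U[%g, %g]",
        if (s$scale != 1) sprintf("%g x ", s$scale) else "",
        s$base, if (s$sign >= 0) "+" else "-", 1, s$lo, s$hi
      )
    }
  }
  cat("<ruleset> ", x$name, "\n", sep = "")
  cat("  N_crit: ", x$n_crit, "  c_envfactor: ", x$c_envfactor,
      "  c_amount: ", x$c_amount, "\n", sep = "")
  cat("  initial: T_life uniform [", x$init_life[1], ", ", x$init_life[2],
      "], T_prol uniform [", x$init_prol[1], ", ", x$init_prol[2], "]\n",
      sep = "")
  cat("  offspring: T_life ", fmt_spec(x$off_life), ", T_prol ",
      fmt_spec(x$off_prol), "\n", sep = "")
  cat("  max target neighbors: ", x$max_target_neighbors, "\n", sep = "")
  invisible(x)
}

# uniform draw on the integer lattice of [lo, hi], inclusive
draw_int_uniform <- function(n, lo, hi) {
  a <- ceiling(lo - 1e-9)
  b <- floor(hi + 1e-9)
  if (b < a) b <- a
  pmin(a + floor(runif(n) * (b - a + 1)), b)
}

draw_spec <- function(spec, n, c_patch, c_envfactor) {
  noise <- draw_int_uniform(n, spec$lo, spec$hi)
  if (spec$kind == "uniform") {
    return(noise)
  }
  det <- round(spec$scale * (spec$base + spec$sign * c_patch / c_envfactor))
  pmax(det + noise, 1)
}

#' Draw lifespan and proliferation-delay parameters
#'
#' Draws `(T_life, T_prol)` for a cell engrafting on a patch with substrate
#' concentration `c_patch`, either as an initial engrafter (both values from
#' the rule set's uniform intervals) or as an offspring cell (the rule set's
#' environment-coupled formula for one of the two, the other uniform).
#'
#' @param rules A [new_ruleset()] object.
#' @param c_patch Substrate concentration(s) at the engraftment patch;
#'   recycled against `n`.
#' @param type `"initial"` or `"offspring"`.
#' @param n Number of draws.
#' @return A tibble with integer columns `t_life` and `t_prol`, `n` rows.
#' @export
#' @examples
#' set.seed(1)
#' draw_engraftment_params(hypothesis1(), c_patch = 19, type = "offspring", n = 3)
draw_engraftment_params <- function(rules, c_patch = 0,
                                    type = c("initial", "offspring"), n = 1) {
  stopifnot(inherits(rules, "ruleset"), all(c_patch >= 0))
  type <- match.arg(type)
  c_patch <- rep_len(c_patch, n)
  if (type == "initial") {
    t_life <- draw_int_uniform(n, rules$init_life[1], rules$init_life[2])
    t_prol <- draw_int_uniform(n, rules$init_prol[1], rules$init_prol[2])
  } else {
    t_life <- draw_spec(rules$off_life, n, c_patch, rules$c_envfactor)
    t_prol <- draw_spec(rules$off_prol, n, c_patch, rules$c_envfactor)
  }
  tibble(t_life = as.integer(t_life), t_prol = as.integer(t_prol))
}

#' Perturb one rule-set parameter by a relative amount
#'
#' Used by the sensitivity protocol: returns a copy of `rules` with one
#' parameter scaled by `1 + delta`. Scalar parameters (`n_crit`, `c_amount`,
#' `c_envfactor`) are scaled directly. The interval parameters `t_life` and
#' `t_prol` scale every component that carries their units: both endpoints
#' of the uniform intervals (initial and offspring), and for an environment
#' -coupled specification the deterministic part (via its `scale` field)
#' together with the noise interval. Integer draws then fall on the integer
#' lattice of the scaled intervals.
#'
#' @param rules A [new_ruleset()] object.
#' @param parameter One of `"n_crit"`, `"c_amount"`, `"c_envfactor"`,
#'   `"t_life"`, `"t_prol"`.
#' @param delta Signed relative change (`+0.05` and `-0.05` in the shipped
#'   protocol).
#' @return A perturbed `ruleset`.
#' @export
#' @examples
#' perturb_ruleset(hypothesis1(), "n_crit", 0.05)$n_crit  # 5.25
#' perturb_ruleset(hypothesis1(), "t_life", -0.05)$init_life  # c(0, 34.2)
perturb_ruleset <- function(rules,
                            parameter = c("n_crit", "c_amount", "c_envfactor",
                                          "t_life", "t_prol"),
                            delta) {
  stopifnot(inherits(rules, "ruleset"), is.numeric(delta), length(delta) == 1)
  parameter <- match.arg(parameter)
  m <- 1 + delta
  scale_spec <- function(s) {
    s$lo <- s$lo * m
    s$hi <- s$hi * m
    if (s$kind == "coupled") s$scale <- s$scale * m
    s
  }
  out <- rules
  switch(parameter,
    n_crit = out$n_crit <- rules$n_crit * m,
    c_amount = out$c_amount <- rules$c_amount * m,
    c_envfactor = out$c_envfactor <- rules$c_envfactor * m,
    t_life = {
      out$init_life <- rules$init_life * m
      out$off_life <- scale_spec(rules$off_life)
    },
    t_prol = {
      out$init_prol <- rules$init_prol * m
      out$off_prol <- scale_spec(rules$off_prol)
    }
  )
  out$name <- sprintf("%s[%s %+.3g%%]", rules$name, parameter, 100 * delta)
  out
}
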