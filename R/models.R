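#' @useDynLib clockloops, .registration = TRUE
#' @importFrom stats runif rnorm sd setNames
#' @importFrom utils modifyList write.csv
"_PACKAGE"

# Architecture registry.  Parameter orders must match src/clockmodels.c.
#
# Symbol conventions (per model, m = number of species):
#   S: maximum transcription rates and translation rate constants, interleaved
#      per gene (S1 = transcription vmax X, S2 = translation X, S3/S4 same for Y)
#   K: transcription affinity constants;  A/B: association/dissociation
#   T/U: nuclear import/export Michaelis pairs (vmax, affinity)
#   D1..Dm: Michaelis degradation vmax per species (Table-1 species order)
#   D(m+1)..D(2m): first-order degradation rate constants per species
#   L1..Lm: degradation affinity constants per species
#   h: Hill coefficient of transcriptional repression (fixed, never searched)
.arch_registry <- local({
  duo_params <- c("S1", "S2", "S3", "S4", "K1", "K2", "A", "B",
                  "T1", "T2", "U1", "U2",
                  paste0("D", 1:12), paste0("L", 1:6), "h")
  list(
    single = list(
      name = "single",
      species = c("mRNA_X", "X", "X_nuc"),
      output = "X_nuc",
      params = c("S1", "S2", "K1", "T1", "T2", "U1", "U2",
                 paste0("D", 1:6), paste0("L", 1:3), "h"),
      linear_degradation = paste0("D", 4:6),
      fixed = "h",
      unused = character(),
      xy_pairs = NULL,
      light_modulated = "D2",
      initfunc = "initmod_single",
      derivfunc = "derivs_single"
    ),
    semi_dual = list(
      name = "semi_dual",
      species = c("mRNA_X", "X", "mRNA_Y", "Y", "XY", "XY_nuc"),
      output = "XY_nuc",
      params = duo_params,
      linear_degradation = paste0("D", 7:12),
      fixed = "h",
      unused = "K2",      # Y transcription is constitutive
      xy_pairs = NULL,
      light_modulated = c("D2", "D5"),
      initfunc = "initmod_duo",
      derivfunc = "derivs_semidual"
    ),
    dual = list(
      name = "dual",
      species = c("mRNA_X", "X", "mRNA_Y", "Y", "XY", "XY_nuc"),
      output = "XY_nuc",
      params = duo_params,
      linear_degradation = paste0("D", 7:12),
      fixed = "h",
      unused = character(),
      # Y-loop parameter = counterpart of the named X-loop parameter
      xy_pairs = c(S1 = "S3", S2 = "S4", K1 = "K2",
                   D1 = "D3", D2 = "D4", D7 = "D9", D8 = "D10",
                   L1 = "L3", L2 = "L4"),
      light_modulated = c("D2", "D5"),
      initfunc = "initmod_duo",
      derivfunc = "derivs_dual"
    ),
    redundant = list(
      name = "redundant",
      species = c("mRNA_X", "X", "X_nuc", "mRNA_Y", "Y", "Y_nuc"),
      output = c("X_nuc", "Y_nuc"),
      params = c("S1", "S2", "S3", "S4", "K1", "K2",
                 paste0("T", 1:4), paste0("U", 1:4),
                 paste0("D", 1:12), paste0("L", 1:6), "h"),
      linear_degradation = paste0("D", 7:12),
      fixed = "h",
      unused = character(),
      xy_pairs = c(S1 = "S3", S2 = "S4", K1 = "K2",
                   T1 = "T3", T2 = "T4", U1 = "U3", U2 = "U4",
                   D1 = "D4", D2 = "D5", D3 = "D6",
                   D7 = "D10", D8 = "D11", D9 = "D12",
                   L1 = "L4", L2 = "L5", L3 = "L6"),
      light_modulated = "D2",
      initfunc = "initmod_red",
      derivfunc = "derivs_redundant"
    )
  )
})

#' Names of the available feedback architectures
#'
#' @return Character vector: `"single"`, `"semi_dual"`, `"dual"`, `"redundant"`.
#' @export
architectures <- function() names(.arch_registry)

#' Construct a circadian clock model
#'
#' Builds one of four competing transcriptional-translational feedback
#' architectures as an ODE model over named species with a named kinetic
#' parameter vector:
#'
#' * `single` (m = 3): one gene; nuclear protein X represses its own
#'   transcription. Output is `X_nuc`.
#' * `semi_dual` (m = 6): gene Y is expressed constitutively; X and Y form a
#'   complex X:Y whose nuclear form represses X transcription. Output `XY_nuc`.
#' * `dual` (m = 6): as `semi_dual` but nuclear X:Y also represses Y
#'   transcription (only the mRNA(Y) equation differs). Output `XY_nuc`.
#' * `redundant` (m = 6): two independent single-type loops; output is the
#'   total nuclear clock protein `X_nuc + Y_nuc`.
#'
#' Rate laws are composed from four primitives (see [hill_repression()],
#' [michaelis()], [mass_action()]): Hill-repressed or constitutive
#' transcription, linear translation, mass-action complex
#' association/dissociation, Michaelis-Menten nuclear import/export, and
#' Michaelis-Menten plus first-order degradation of every species.
#' Units are nM and hours throughout.
#'
#' @param architecture One of [architectures()].
#' @param params Optional named kinetic parameter vector; defaults to
#'   [reference_parameters()] for the architecture. Every required field must
#'   be present and strictly positive.
#' @return An object of class `clock_model`: a list with elements
#'   `architecture`, `species`, `output`, `params`, and internal metadata.
#' @examples
#' m <- clock_model("dual")
#' m$species
#' @export
clock_model <- function(architecture = architectures(), params = NULL) {
  architecture <- match.arg(architecture)
  arch <- .arch_registry[[architecture]]
  if (is.null(params)) params <- reference_parameters(architecture)
  params <- validate_params(architecture, params)
  structure(
    list(architecture = architecture,
         n_equations = length(arch$species),
         species = arch$species,
         output = arch$output,
         params = params,
         arch = arch),
    class = "clock_model")
}

#' @export
print.clock_model <- function(x, ...) {
  cat(sprintf("<clock_model: %s feedback, m = %d>\n",
              x$architecture, x$n_equations))
  cat("  species:", paste(x$species, collapse = ", "), "\n")
  cat("  output :", paste(x$output, collapse = " + "), "\n")
  cat(sprintf("  %d kinetic parameters (h = %.1f fixed)\n",
              length(searched_parameters(x$architecture)), x$params[["h"]]))
  invisible(x)
}

#' Reference kinetic parameter values
#'
#' All maximum rates, affinity constants, translation and
#' association/dissociation constants are 1.0 in their natural units
#' (nM h^-1, nM, h^-1, nM^-1 h^-1); first-order degradation rate constants
#' are 0.01 h^-1; the Hill coefficient is 4.0 and is fixed (never searched
#' or perturbed).
#'
#' @param architecture One of [architectures()].
#' @return Named numeric vector in the model's canonical parameter order.
#' @export
reference_parameters <- function(architecture = architectures()) {
  architecture <- match.arg(architecture)
  arch <- .arch_registry[[architecture]]
  p <- setNames(rep(1.0, length(arch$params)), arch$params)
  p[arch$linear_degradation] <- 0.01
  p["h"] <- 4.0
  p
}

#' Kinetic parameters subject to search and perturbation
#'
#' Everything except the fixed Hill coefficient and, for the semi-dual model,
#' the unused Y-transcription affinity (Y is constitutive).
#'
#' @param architecture One of [architectures()].
#' @return Character vector of parameter names.
#' @export
searched_parameters <- function(architecture = architectures()) {
  architecture <- match.arg(architecture)
  arch <- .arch_registry[[architecture]]
  setdiff(arch$params, c(arch$fixed, arch$unused))
}

#' X-loop / Y-loop parameter pairing for the symmetric architectures
#'
#' @param architecture `"dual"` or `"redundant"`.
#' @return Named character vector mapping each X-loop parameter to its Y-loop
#'   counterpart.
#' @export
loop_pairs <- function(architecture = c("dual", "redundant")) {
  architecture <- match.arg(architecture)
  .arch_registry[[architecture]]$xy_pairs
}

validate_params <- function(architecture, params) {
  arch <- .arch_registry[[architecture]]
  nm <- names(params)
  missing <- setdiff(arch$params, nm)
  if (length(missing))
    stop(sprintf("model '%s' is missing parameter(s): %s",
                 architecture, paste(missing, collapse = ", ")), call. = FALSE)
  extra <- setdiff(nm, arch$params)
  if (length(extra))
    stop(sprintf("unknown parameter(s) for model '%s': %s",
                 architecture, paste(extra, collapse = ", ")), call. = FALSE)
  p <- as.numeric(params[arch$params])
  names(p) <- arch$params
  if (any(!is.finite(p)) || any(p <= 0))
    stop("all kinetic parameters must be finite and strictly positive",
         call. = FALSE)
  p
}

# ---- composable rate-law primitives -----------------------------------------

#' Rate-law primitives
#'
#' The four building blocks from which every model equation is composed.
#' `hill_repression` is the repressed transcription rate
#' \eqn{v K^h / (K^h + r^h)}; `michaelis` is \eqn{v s / (K + s)} (used for
#' nuclear transport and saturable degradation); `mass_action` is the
#' bilinear association rate \eqn{k a b}; first-order terms are plain
#' products and need no helper.
#'
#' @param vmax,K,h,repressor,s,k,a,b Rates, affinities and concentrations
#'   (nM, h); see the formulas above.
#' @return Reaction rate in nM h^-1.
#' @name rate_laws
NULL

#' @rdname rate_laws
#' @export
hill_repression <- function(vmax, K, h, repressor) {
  Kh <- K^h
  vmax * Kh / (Kh + ifelse(repressor > 0, repressor^h, 0))
}

#' @rdname rate_laws
#' @export
michaelis <- function(vmax, K, s) vmax * s / (K + s)

#' @rdname rate_laws
#' @export
mass_action <- function(k, a, b) k * a * b

#' Evaluate a model's derivative vector in R
#'
#' A pure-R transcription of the model equations, composed from the rate-law
#' primitives. The compiled right-hand side used by [integrate_clock()] must
#' agree with this function to rounding error; the package's tests assert
#' that. `light_factor` multiplies the light-modulated degradation vmax
#' (cytoplasmic X, and the cytoplasmic X:Y complex where present).
#'
#' @param model A [clock_model()].
#' @param state Named or ordered non-negative state vector (one value per
#'   species).
#' @param params Optional parameter override.
#' @param light_factor Multiplier on the light-modulated degradation vmax
#'   (1 = constant darkness).
#' @return Numeric derivative vector, one entry per species (nM h^-1).
#' @export
clock_derivatives <- function(model, state, params = NULL,
                              light_factor = 1) {
  stopifnot(inherits(model, "clock_model"))
  p <- as.list(if (is.null(params)) model$params
               else validate_params(model$architecture, params))
  s <- as.numeric(state)
  names(s) <- model$species
  s <- as.list(s)
  h <- p$h
  degr <- function(sp, i, lf = 1)
    lf * michaelis(p[[paste0("D", i)]], p[[paste0("L", i)]], s[[sp]]) +
      p[[paste0("D", i + model$n_equations)]] * s[[sp]]
  out <- switch(model$architecture,
    single = {
      imp <- michaelis(p$T1, p$T2, s$X)
      exp_ <- michaelis(p$U1, p$U2, s$X_nuc)
      c(hill_repression(p$S1, p$K1, h, s$X_nuc) - degr("mRNA_X", 1),
        p$S2 * s$mRNA_X - imp + exp_ - degr("X", 2, light_factor),
        imp - exp_ - degr("X_nuc", 3))
    },
    semi_dual = ,
    dual = {
      assoc <- mass_action(p$A, s$X, s$Y)
      dissoc <- p$B * s$XY
      imp <- michaelis(p$T1, p$T2, s$XY)
      exp_ <- michaelis(p$U1, p$U2, s$XY_nuc)
      txY <- if (model$architecture == "dual")
        hill_repression(p$S3, p$K2, h, s$XY_nuc) else p$S3
      c(hill_repression(p$S1, p$K1, h, s$XY_nuc) - degr("mRNA_X", 1),
        p$S2 * s$mRNA_X - assoc + dissoc - degr("X", 2, light_factor),
        txY - degr("mRNA_Y", 3),
        p$S4 * s$mRNA_Y - assoc + dissoc - degr("Y", 4),
        assoc - dissoc - imp + exp_ - degr("XY", 5, light_factor),
        imp - exp_ - degr("XY_nuc", 6))
    },
    redundant = {
      impx <- michaelis(p$T1, p$T2, s$X)
      expx <- michaelis(p$U1, p$U2, s$X_nuc)
      impy <- michaelis(p$T3, p$T4, s$Y)
      expy <- michaelis(p$U3, p$U4, s$Y_nuc)
      c(hill_repression(p$S1, p$K1, h, s$X_nuc) - degr("mRNA_X", 1),
        p$S2 * s$mRNA_X - impx + expx - degr("X", 2, light_factor),
        impx - expx - degr("X_nuc", 3),
        hill_repression(p$S3, p$K2, h, s$Y_nuc) - degr("mRNA_Y", 4),
        p$S4 * s$mRNA_Y - impy + expy - degr("Y", 5),
        impy - expy - degr("Y_nuc", 6))
    })
  setNames(out, model$species)
}

# ---- kinetic-symmetry (rho) constrained search spaces -----------------------

#' Search interval for a Y-loop parameter under kinetic symmetry rho
#'
#' In the dual and redundant models the search range of each Y-loop kinetic
#' parameter is tied to the value drawn for its X-loop counterpart by the
#' symmetry parameter \eqn{\rho \ge 0}: the admissible band is
#' \eqn{[x / (1 + \rho),\; x (1 + \rho)]} intersected with the global search
#' bounds. At \eqn{\rho = 0} the band collapses to the X value (perfect
#' kinetic symmetry); at \eqn{\rho \ge 99} the band covers the whole 0.1-10
#' fold global range, so both loops are independently assigned.
#'
#' @param x_value Value of the X-loop parameter (must lie within
#'   `global_bounds`).
#' @param rho Non-negative symmetry parameter.
#' @param global_bounds Length-2 numeric, the global lower/upper search bound
#'   for this parameter.
#' @return Length-2 numeric interval for the Y-loop parameter.
#' @examples
#' y_loop_bounds(2, 0, c(0.1, 10))    # c(2, 2)
#' y_loop_bounds(2, 99, c(0.1, 10))   # c(0.1, 10)
#' @export
y_loop_bounds <- function(x_value, rho, global_bounds) {
  stopifnot(length(global_bounds) == 2, global_bounds[1] > 0,
            global_bounds[2] >= global_bounds[1], rho >= 0)
  if (x_value < global_bounds[1] || x_value > global_bounds[2])
    stop("x_value lies outside the global search bounds", call. = FALSE)
  c(max(global_bounds[1], x_value / (1 + rho)),
    min(global_bounds[2], x_value * (1 + rho)))
}

#' Global search bounds for every searched parameter
#'
#' Each kinetic parameter is varied multiplicatively around its reference
#' value, by default 0.1-10 fold.
#'
#' @param architecture One of [architectures()].
#' @param fold Length-2 multiplicative range (default `c(0.1, 10)`).
#' @return Matrix with rows `lower`, `upper` and one column per searched
#'   parameter.
#' @export
parameter_bounds <- function(architecture = architectures(),
                             fold = c(0.1, 10)) {
  architecture <- match.arg(architecture)
  stopifnot(length(fold) == 2, fold[1] > 0, fold[2] >= fold[1])
  ref <- reference_parameters(architecture)[searched_parameters(architecture)]
  rbind(lower = ref * fold[1], upper = ref * fold[2])
}
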