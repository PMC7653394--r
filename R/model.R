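#' RCP model
#'
#' A reactant-catalyst-product model: a set of named agent types together
#' with a list of reaction primitives (see [reactions]) acting on point
#' configurations in continuous space.  Models built from these primitives
#' can be simulated exactly ([simulate_rcp()]) and analysed with the
#' perturbation-expansion moment equations ([solve_mean_field()],
#' [solve_spatial_cumulant()], [spacetime_cumulant()]).
#'
#' @param types character vector of unique type names.
#' @param reactions list of reactions built with the constructors in
#'   [reactions].
#' @param dimension spatial dimension, 1 or 2.
#' @return An object of class `rcp_model`.
#' @seealso [sslm_model()], [hp_model()], [expand_auxiliary()],
#'   [validate_model()]
#' @export
rcp_model <- function(types, reactions = list(), dimension = 2L) {
  stopifnot(is.character(types), length(types) >= 1L,
            !anyDuplicated(types), is.list(reactions),
            dimension %in% c(1L, 2L))
  if (length(reactions) &&
      !all(vapply(reactions, inherits, TRUE, "rcp_reaction")))
    stop("all reactions must be built with the reaction constructors")
  m <- structure(
    list(types = types, reactions = reactions,
         dimension = as.integer(dimension)),
    class = "rcp_model")
  diag <- validate_model(m)
  if (!diag$ok)
    stop("invalid model: ", paste(diag$messages, collapse = "; "))
  m
}

#' @export
print.rcp_model <- function(x, ...) {
  cat(sprintf("<rcp_model> %d type(s) [%s], d = %d, %d reaction(s)\n",
              length(x$types), paste(x$types, collapse = ", "),
              x$dimension, length(x$reactions)))
  for (r in x$reactions) cat("  ", format_reaction(r), "\n", sep = "")
  invisible(x)
}

n_types <- function(model) length(model$types)

type_index <- function(model, type) {
  i <- match(type, model$types)
  if (anyNA(i)) stop("unknown type(s): ",
                     paste(type[is.na(i)], collapse = ", "))
  i
}

reaction_type_refs <- function(r) {
  switch(r$kind,
    constant_death = c(r$reactant),
    pairwise_death = c(r$reactant, r$catalyst),
    birth_dispersal = c(r$parent, r$offspring),
    catalyzed_conversion = c(r$reactant, r$catalyst, r$product),
    constant_conversion = c(r$reactant, r$product))
}

#' Validate an RCP model
#'
#' Checks type references, kernel dimensions and rate signs; returns a
#' diagnostics object rather than throwing, so malformed configurations can
#' be reported in full.
#'
#' @param model an object with the structure of an [rcp_model()].
#' @return A list with elements `ok` (logical) and `messages` (character).
#' @export
validate_model <- function(model) {
  msgs <- character()
  for (i in seq_along(model$reactions)) {
    r <- model$reactions[[i]]
    refs <- reaction_type_refs(r)
    bad <- setdiff(refs, model$types)
    if (length(bad))
      msgs <- c(msgs, sprintf("reaction %d (%s): unknown type(s) %s",
                              i, r$kind, paste(bad, collapse = ", ")))
    if (!is.null(r$rate) && (!is.numeric(r$rate) || r$rate < 0))
      msgs <- c(msgs, sprintf("reaction %d (%s): negative rate", i, r$kind))
    k <- reaction_kernel(r)
    if (!is.null(k)) {
      if (k$integral < 0)
        msgs <- c(msgs, sprintf("reaction %d: negative kernel integral", i))
      if (k$dimension != model$dimension)
        msgs <- c(msgs, sprintf(
          "reaction %d (%s): kernel dimension %d != model dimension %d",
          i, r$kind, k$dimension, model$dimension))
    }
  }
  list(ok = length(msgs) == 0L, messages = msgs)
}

model_kernels <- function(model) {
  ks <- lapply(model$reactions, reaction_kernel)
  ks[!vapply(ks, is.null, TRUE)]
}

max_truncation <- function(model) {
  ks <- model_kernels(model)
  if (!length(ks)) return(0)
  tr <- vapply(ks, function(k) {
    if (is.null(k$truncation)) Inf else k$truncation
  }, 0)
  max(tr)
}

#' Spatial and stochastic logistic model (SSLM)
#'
#' Factory for the one-type logistic point process: density-independent
#' death at rate `m`, density-dependent death through a competition kernel
#' \eqn{a^-} with integral `Aminus`, and reproduction with a dispersal
#' kernel \eqn{a^+} with integral `Aplus`.  Its mean-field limit is the
#' logistic equation \eqn{dq/dt = (A^+ - m)q - A^- q^2} with carrying
#' capacity \eqn{q^* = (A^+ - m)/A^-}.
#'
#' @param Aplus,Aminus integrals of the reproduction and competition
#'   kernels.
#' @param m density-independent death rate.
#' @param epsilon kernel length-scale parameter (both kernels share it by
#'   default).
#' @param truncation truncation radius for both kernels (`NULL` for
#'   untruncated; the simulator requires truncated kernels).
#' @param shape kernel shape.
#' @param dimension spatial dimension.
#' @param type name of the single agent type.
#' @return an [rcp_model()].
#' @export
sslm_model <- function(Aplus = 2, Aminus = 1, m = 1, epsilon = 1 / sqrt(2),
                       truncation = 12, shape = "gaussian", dimension = 2L,
                       type = "X") {
  ap <- rcp_kernel(shape, Aplus, epsilon, dimension, truncation)
  am <- rcp_kernel(shape, Aminus, epsilon, dimension, truncation)
  rcp_model(
    types = type,
    reactions = list(
      constant_death(type, m),
      pairwise_death(type, type, am),
      birth_dispersal(type, ap)),
    dimension = dimension)
}

#' Host-parasite model
#'
#' Factory for the two-type host-parasite (equivalently predator-prey)
#' model: hosts `H` reproduce with kernel \eqn{a^+} (integral `Aplus`) and
#' suffer density-dependent death from other hosts with kernel \eqn{a^-}
#' (integral `Aminus`); parasitized hosts `P` convert uninfected hosts into
#' parasitized hosts in place with kernel \eqn{b} (integral `B`) and die at
#' constant rate `m`.  The mean-field system
#' \deqn{dq_H/dt = q_H (A^+ - A^- q_H - B q_P), \quad
#'       dq_P/dt = q_P (B q_H - m)}
#' has the coexistence equilibrium \eqn{q_H^* = m/B},
#' \eqn{q_P^* = (A^+ - A^- q_H^*)/B} and shows damped oscillations for the
#' default parameters.
#'
#' @param Aplus,Aminus,B kernel integrals (reproduction, competition,
#'   infection).
#' @param m parasite death rate.
#' @param epsilon shared kernel length-scale parameter.
#' @param truncation truncation radius for all kernels.
#' @param shape kernel shape.
#' @param dimension spatial dimension.
#' @return an [rcp_model()] with types `H` and `P`.
#' @export
hp_model <- function(Aplus = 1, Aminus = 0.1, B = 1, m = 1,
                     epsilon = 1 / sqrt(2), truncation = 6,
                     shape = "gaussian", dimension = 2L) {
  ap <- rcp_kernel(shape, Aplus, epsilon, dimension, truncation)
  am <- rcp_kernel(shape, Aminus, epsilon, dimension, truncation)
  b  <- rcp_kernel(shape, B, epsilon, dimension, truncation)
  rcp_model(
    types = c("H", "P"),
    reactions = list(
      birth_dispersal("H", ap),
      pairwise_death("H", "H", am),
      catalyzed_conversion("H", "P", "P", b),
      constant_death("P", m)),
    dimension = dimension)
}

#' Build a model from a name or configuration
#'
#' Convenience dispatcher: `make_model("sslm", ...)` and
#' `make_model("hp", ...)` forward to the factories; a list of reactions
#' builds a custom model.
#'
#' @param name `"sslm"`, `"hp"`, or a list of reactions.
#' @param ... parameters passed to the factory, or `types`/`dimension` for a
#'   custom reaction list.
#' @return an [rcp_model()].
#' @export
make_model <- function(name, ...) {
  if (is.list(name)) return(rcp_model(reactions = name, ...))
  switch(match.arg(name, c("sslm", "hp")),
         sslm = sslm_model(...),
         hp = hp_model(...))
}

## ---- configuration round trip --------------------------------------------

kernel_to_config <- function(k) {
  c(list(shape = k$shape, integral = k$integral, epsilon = k$epsilon,
         dimension = k$dimension),
    if (!is.null(k$truncation)) list(truncation = k$truncation))
}

kernel_from_config <- function(cfg) {
  for (f in c("shape", "integral", "epsilon"))
    if (is.null(cfg[[f]])) stop("kernel config misses field '", f, "'")
  rcp_kernel(cfg$shape, cfg$integral, cfg$epsilon,
             if (is.null(cfg$dimension)) 2L else as.integer(cfg$dimension),
             cfg$truncation)
}

reaction_to_config <- function(r) {
  out <- unclass(r)
  if (!is.null(out$kernel)) out$kernel <- kernel_to_config(out$kernel)
  out
}

reaction_from_config <- function(cfg) {
  if (is.null(cfg$kind)) stop("reaction config misses field 'kind'")
  need <- function(f)
    if (is.null(cfg[[f]])) stop("reaction '", cfg$kind,
                                "' misses field '", f, "'") else cfg[[f]]
  k <- if (!is.null(cfg$kernel)) kernel_from_config(cfg$kernel)
  switch(cfg$kind,
    constant_death = constant_death(need("reactant"), need("rate")),
    pairwise_death = pairwise_death(need("reactant"), need("catalyst"),
                                    k %||% stop("missing kernel")),
    birth_dispersal = birth_dispersal(need("parent"),
                                      k %||% stop("missing kernel"),
                                      cfg$offspring %||% cfg$parent),
    catalyzed_conversion = catalyzed_conversion(
      need("reactant"), need("catalyst"), need("product"),
      k %||% stop("missing kernel")),
    constant_conversion = constant_conversion(need("reactant"),
                                              need("product"), need("rate")),
    stop("unknown reaction kind '", cfg$kind, "'"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize / deserialize a model configuration
#'
#' `model_to_config()` turns a model into a plain nested list (suitable for
#' YAML/JSON); `model_from_config()` inverts it.  The round trip
#' parse-serialize-parse is lossless.
#'
#' @param model an [rcp_model()].
#' @param config a nested list as produced by `model_to_config()`.
#' @return a list, respectively an [rcp_model()].
#' @export
model_to_config <- function(model) {
  list(types = as.list(model$types),
       dimension = model$dimension,
       reactions = lapply(model$reactions, reaction_to_config))
}

#' @rdname model_to_config
#' @export
model_from_config <- function(config) {
  rcp_model(types = unlist(config$types),
            reactions = lapply(config$reactions, reaction_from_config),
            dimension = as.integer(config$dimension %||% 2L))
}
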