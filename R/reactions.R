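#' Reaction primitives
#'
#' Constructors for the reaction primitives of an RCP (reactant - catalyst -
#' product) model.  Each reaction names agent types by their character
#' labels; rates of kernel-mediated reactions are given by an
#' [rcp_kernel()].  The primitives are:
#'
#' * `constant_death(type, rate)`: density-independent death of `type` at a
#'   constant per-capita rate.
#' * `pairwise_death(reactant, catalyst, kernel)`: density-dependent death;
#'   an agent of type `reactant` at `x` dies at rate
#'   \eqn{\sum_y a(x - y)} summed over catalysts (competition).  `catalyst`
#'   may be a vector of types, in which case the sum runs over their union
#'   (used by the auxiliary model, where original and new agents jointly
#'   catalyze).
#' * `birth_dispersal(parent, kernel, offspring = parent)`: each parent
#'   produces offspring at per-unit-area rate `kernel(x - y)` around itself;
#'   the total per-capita birth rate is the kernel integral.  Offspring are
#'   of the parent's type unless `offspring` says otherwise (used by the
#'   auxiliary construction, where every newborn is a "new" agent).
#' * `catalyzed_conversion(reactant, catalyst, product, kernel)`: the
#'   reactant turns into the product \emph{in place} (same location, same
#'   agent identity) at rate \eqn{\sum_y b(x - y)} over catalysts
#'   (e.g. infection of hosts by parasitized hosts).
#' * `constant_conversion(reactant, product, rate)`: spontaneous in-place
#'   type change at a constant rate (needed by the auxiliary model, where
#'   the death of an original agent converts it into an inert past agent).
#'
#' @param type,reactant,catalyst,parent,product,offspring character type
#'   labels.
#' @param rate non-negative constant rate.
#' @param kernel an [rcp_kernel()].
#' @return A list of class `rcp_reaction` describing the reaction.
#' @name reactions
NULL

new_reaction <- function(kind, ...) {
  structure(c(list(kind = kind), list(...)), class = "rcp_reaction")
}

#' @rdname reactions
#' @export
constant_death <- function(type, rate) {
  stopifnot(is.character(type), rate >= 0)
  new_reaction("constant_death", reactant = type, rate = as.numeric(rate))
}

#' @rdname reactions
#' @export
pairwise_death <- function(reactant, catalyst, kernel) {
  stopifnot(is.character(reactant), is.character(catalyst), is_kernel(kernel))
  new_reaction("pairwise_death", reactant = reactant, catalyst = catalyst,
               kernel = kernel)
}

#' @rdname reactions
#' @export
birth_dispersal <- function(parent, kernel, offspring = parent) {
  stopifnot(is.character(parent), is.character(offspring), is_kernel(kernel))
  new_reaction("birth_dispersal", parent = parent, offspring = offspring,
               kernel = kernel)
}

#' @rdname reactions
#' @export
catalyzed_conversion <- function(reactant, catalyst, product, kernel) {
  stopifnot(is.character(reactant), is.character(catalyst),
            is.character(product), is_kernel(kernel))
  new_reaction("catalyzed_conversion", reactant = reactant,
               catalyst = catalyst, product = product, kernel = kernel)
}

#' @rdname reactions
#' @export
constant_conversion <- function(reactant, product, rate) {
  stopifnot(is.character(reactant), is.character(product), rate >= 0)
  new_reaction("constant_conversion", reactant = reactant, product = product,
               rate = as.numeric(rate))
}

#' @export
print.rcp_reaction <- function(x, ...) {
  cat(format_reaction(x), "\n")
  invisible(x)
}

format_reaction <- function(x) {
  switch(x$kind,
    constant_death = sprintf("%s -> 0  (rate %g)", x$reactant, x$rate),
    pairwise_death = sprintf("%s -> 0  (catalyst %s, kernel %s A=%g)",
                             x$reactant, paste(x$catalyst, collapse = "+"),
                             x$kernel$shape, x$kernel$integral),
    birth_dispersal = sprintf("%s -> %s + %s  (kernel %s A=%g)",
                              x$parent, x$parent, x$offspring,
                              x$kernel$shape, x$kernel$integral),
    catalyzed_conversion = sprintf(
      "%s -> %s  (catalyst %s, kernel %s A=%g)",
      x$reactant, x$product, paste(x$catalyst, collapse = "+"),
      x$kernel$shape, x$kernel$integral),
    constant_conversion = sprintf("%s -> %s  (rate %g)",
                                  x$reactant, x$product, x$rate))
}

reaction_kernel <- function(x) x$kernel  # NULL for constant-rate reactions
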