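#' Expand a model into its auxiliary (original / past / new) form
#'
#' The auxiliary model tracks, from a fixed reference time, both the initial
#' and the current configuration of the primary model within a single Markov
#' state.  Each agent type expands into tagged states:
#'
#' * \emph{original} states `(i>j)`: agents present at the reference time
#'   with initial type `i`, still alive, currently of type `j` (types can
#'   change through in-place conversions);
#' * \emph{new} states `(+>j)`: agents born after the reference time,
#'   currently of type `j`;
#' * \emph{past} states `(i>+)` (inert): agents present at the reference
#'   time with initial type `i` that have since died.
#'
#' Reactions expand so that the projection onto current types of the live
#' states reproduces the primary model exactly: death of an original agent
#' becomes an in-place conversion to the corresponding past state, death of
#' a new agent is a true death, every birth produces a new-state offspring,
#' and conversions act on the current-type tag while preserving the
#' initial-type tag.  Kernel-mediated rates are catalyzed by \emph{all} live
#' agents of the catalyst's current type, original or new.  For a model
#' without conversions the construction collapses to the classical three
#' states original / new / past per type.
#'
#' The initial configuration of the primary model is recovered as the union
#' of original and past agents, the current configuration as the union of
#' original and new agents; this is what makes the spatio-temporal cumulant
#' of the primary model a sum of four spatial cumulants of the auxiliary
#' model.
#'
#' @param model an [rcp_model()].
#' @return An object of classes `rcp_auxiliary_model` and `rcp_model`, with
#'   extra fields `states` (a data frame with columns `state`, `init`,
#'   `cur`, `status`) and `primary` (the input model).
#' @export
expand_auxiliary <- function(model) {
  types <- model$types

  ## current-type transition map induced by conversion reactions
  conv_edges <- unique(do.call(rbind, c(list(data.frame(from = character(),
                                                        to = character())),
    lapply(model$reactions, function(r) {
      if (r$kind %in% c("catalyzed_conversion", "constant_conversion"))
        data.frame(from = r$reactant, to = r$product)
      else NULL
    }))))
  closure <- function(start) {
    cur <- unique(start)
    repeat {
      nxt <- unique(c(cur, conv_edges$to[conv_edges$from %in% cur]))
      if (length(nxt) == length(cur)) return(sort(nxt))
      cur <- nxt
    }
  }

  ## live original states (i>j): start at (i>i), close under conversions
  orig <- do.call(rbind, lapply(types, function(i) {
    data.frame(init = i, cur = closure(i), stringsAsFactors = FALSE)
  }))

  ## new states (+>j): types reachable from birth offspring
  birth_offspring <- unique(unlist(lapply(model$reactions, function(r) {
    if (r$kind == "birth_dispersal") r$offspring else NULL
  })))
  new_cur <- if (length(birth_offspring)) closure(birth_offspring)
             else character()

  ## past states (i>+): reachable if some live (i>j) can die
  dies <- function(cur_type) any(vapply(model$reactions, function(r) {
    r$kind %in% c("constant_death", "pairwise_death") && r$reactant == cur_type
  }, TRUE))
  past_init <- unique(orig$init[vapply(orig$cur, dies, TRUE)])

  st <- rbind(
    data.frame(state = sprintf("%s>%s", orig$init, orig$cur),
               init = orig$init, cur = orig$cur, status = "original",
               stringsAsFactors = FALSE),
    if (length(new_cur))
      data.frame(state = sprintf("+>%s", new_cur), init = "+", cur = new_cur,
                 status = "new", stringsAsFactors = FALSE),
    if (length(past_init))
      data.frame(state = sprintf("%s>+", past_init), init = past_init,
                 cur = "+", status = "past", stringsAsFactors = FALSE))

  live <- st[st$status != "past", , drop = FALSE]
  live_of_cur <- function(j) live$state[live$cur == j]
  orig_state <- function(i, j) sprintf("%s>%s", i, j)
  past_state <- function(i) sprintf("%s>+", i)
  ## state an agent in live state s moves to when its current type becomes j
  moved <- function(s) {
    row <- st[match(s, st$state), ]
    function(j) if (row$status == "new") sprintf("+>%s", j)
                else orig_state(row$init, j)
  }

  rx <- list()
  add <- function(r) rx[[length(rx) + 1L]] <<- r
  for (r in model$reactions) {
    switch(r$kind,
      constant_death = {
        for (s in live_of_cur(r$reactant)) {
          row <- st[match(s, st$state), ]
          if (row$status == "new") add(constant_death(s, r$rate))
          else add(constant_conversion(s, past_state(row$init), r$rate))
        }
      },
      pairwise_death = {
        cats <- unique(unlist(lapply(r$catalyst, live_of_cur)))
        for (s in live_of_cur(r$reactant)) {
          row <- st[match(s, st$state), ]
          if (row$status == "new") add(pairwise_death(s, cats, r$kernel))
          else add(catalyzed_conversion(s, cats, past_state(row$init),
                                        r$kernel))
        }
      },
      birth_dispersal = {
        for (s in live_of_cur(r$parent))
          add(birth_dispersal(s, r$kernel,
                              offspring = sprintf("+>%s", r$offspring)))
      },
      catalyzed_conversion = {
        cats <- unique(unlist(lapply(r$catalyst, live_of_cur)))
        for (s in live_of_cur(r$reactant)) {
          mv <- moved(s)
          add(catalyzed_conversion(s, cats, mv(r$product), r$kernel))
        }
      },
      constant_conversion = {
        for (s in live_of_cur(r$reactant)) {
          mv <- moved(s)
          add(constant_conversion(s, mv(r$product), r$rate))
        }
      })
  }

  aux <- rcp_model(types = st$state, reactions = rx,
                   dimension = model$dimension)
  aux$states <- st
  aux$primary <- model
  class(aux) <- c("rcp_auxiliary_model", class(aux))
  aux
}

#' @export
print.rcp_auxiliary_model <- function(x, ...) {
  cat(sprintf("<rcp_auxiliary_model> of a %d-type primary model\n",
              length(x$primary$types)))
  cat(sprintf("  states: %s\n", paste(x$states$state, collapse = ", ")))
  cat(sprintf("  %d reaction(s)\n", length(x$reactions)))
  invisible(x)
}

## index sets used when assembling primary-model quantities from the
## auxiliary model
aux_first_member_states <- function(aux, i) {
  st <- aux$states
  which(st$init == i)                       # live originals + past, initial type i
}

aux_second_member_states <- function(aux, j) {
  st <- aux$states
  which(st$cur == j & st$status != "past")  # live agents with current type j
}

aux_original_states <- function(aux) which(aux$states$status == "original")
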