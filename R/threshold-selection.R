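#' Default cost grid
#'
#' Costs 0.050 to 0.500 in steps of 0.025 — 19 settings.
#'
#' @param from,to,by Grid limits and step.
#' @return Strictly increasing numeric vector of costs in `(0, 1)`.
#' @export
cost_grid <- function(from = 0.050, to = 0.500, by = 0.025) {
  costs <- seq(from, to, by = by)
  if (any(diff(costs) <= 0) || any(costs <= 0 | costs >= 1)) {
    abort("Cost grid must be strictly increasing within (0, 1).")
  }
  costs
}

binarize_all <- function(cms, cost) purrr::map(cms, binarize_by_cost, cost = cost)

#' Small-world feasibility of each cost setting
#'
#' A cost is feasible when the group-mean global efficiency of the observed
#' networks lies strictly between that of edge-matched ring lattices and
#' degree-matched random (degree-preserving rewired) references:
#' `E_lattice < E_observed < E_random`. Reference efficiencies are means over
#' `n_realizations` realizations per network.
#'
#' @param blocks A dataset tibble with a `cm` list-column (see
#'   [compute_connectivity()]).
#' @param costs Cost grid.
#' @param n_realizations Random-reference realizations per network
#'   (default 20).
#' @param seed Seed for the rewiring.
#' @return A tibble with `cost`, `e_obs`, `e_random`, `e_lattice`,
#'   `feasible`.
#' @export
smallworld_feasible_costs <- function(blocks, costs = cost_grid(),
                                      n_realizations = 20L, seed = 1L) {
  cms <- check_cms(blocks)
  purrr::map_dfr(seq_along(costs), function(ci) {
    nets <- binarize_all(cms, costs[ci])
    e_obs <- mean(purrr::map_dbl(nets, global_efficiency))
    e_rand <- mean(purrr::map_dbl(seq_along(nets), function(ni) {
      refs <- reference_graphs(nets[[ni]], "random", n_realizations,
                               seed = seed + 1000L * ci + ni)
      mean(purrr::map_dbl(refs, global_efficiency))
    }))
    # Lattice reference is deterministic and identical for equal (J, m).
    e_latt <- global_efficiency(reference_graphs(nets[[1L]], "lattice")[[1L]])
    tibble::tibble(cost = costs[ci], e_obs = e_obs, e_random = e_rand,
                   e_lattice = e_latt,
                   feasible = e_latt < e_obs & e_obs < e_rand)
  })
}

check_cms <- function(blocks) {
  if (!"cm" %in% names(blocks)) {
    abort("`blocks` needs a `cm` list-column; run compute_connectivity() first.")
  }
  blocks$cm
}

#' Similarity of each cost's degree distribution to the cost-average
#'
#' Per subject and condition: the degree vector at every cost, their average
#' across costs, and the Pearson correlation of each per-cost degree vector
#' with that average; scores are means of these correlations over all
#' blocks. The cost with the highest score yields the network most similar
#' to the average characteristics. A constant degree vector has an undefined
#' correlation and contributes 0 with a warning.
#'
#' @inheritParams smallworld_feasible_costs
#' @return A tibble with `cost`, `similarity`.
#' @export
degree_similarity_score <- function(blocks, costs = cost_grid()) {
  cms <- check_cms(blocks)
  per_block <- purrr::map(cms, function(cm) {
    degs <- vapply(costs, function(co) degree_centrality(binarize_by_cost(cm, co)),
                   numeric(nrow(cm$z)))
    avg <- rowMeans(degs)
    vapply(seq_along(costs), function(ci) {
      dv <- degs[, ci]
      if (sd(dv) == 0 || sd(avg) == 0) {
        warn("Constant degree vector; correlation contribution set to 0.")
        return(0)
      }
      cor(dv, avg)
    }, numeric(1))
  })
  tibble::tibble(cost = costs,
                 similarity = rowMeans(do.call(cbind, per_block)))
}

#' Stability of the community count across participants
#'
#' Per condition and cost: the number of communities found by
#' [newman_communities()] for every participant, and the sample standard
#' deviation (denominator `n - 1`) of those counts across participants. The
#' two conditions' standard deviations are averaged into one value per cost;
#' lower means more stable.
#'
#' @inheritParams smallworld_feasible_costs
#' @param gamma Resolution parameter for community detection (default 1).
#' @return A tibble with `cost`, `stability_sd`.
#' @export
community_stability_score <- function(blocks, costs = cost_grid(),
                                      gamma = 1.0) {
  cms <- check_cms(blocks)
  conds <- as.character(blocks$condition)
  purrr::map_dfr(costs, function(co) {
    counts <- purrr::map_int(cms, function(cm) {
      newman_communities(binarize_by_cost(cm, co), gamma)$n_communities
    })
    sds <- vapply(unique(conds), function(cd) {
      x <- counts[conds == cd]
      if (length(x) < 2L) 0 else sd(x)
    }, numeric(1))
    tibble::tibble(cost = co, stability_sd = mean(sds))
  })
}

#' Select the single cost threshold by the three criteria
#'
#' 1. Small-world feasibility restricts the grid to costs where the observed
#'    group-mean global efficiency lies between lattice and random
#'    references. 2. Degree-distribution similarity (higher is better) and
#'    3. community-count stability (lower SD is better) are computed over
#'    the feasible costs only. How the last two criteria combine is not
#'    canonical; the default combines the two rankings by minimal rank sum
#'    (similarity descending, stability SD ascending; ties by the smaller
#'    cost). `rule = "similarity_first"` or `"stability_first"` instead
#'    picks the best cost under one criterion, breaking ties with the other.
#'
#' @inheritParams smallworld_feasible_costs
#' @param gamma Resolution parameter for the stability criterion.
#' @param rule Combination rule, see above.
#' @return An object of class `cost_selection`: a `table` tibble (`cost`,
#'   `feasible`, efficiencies, `similarity`, `stability_sd`, ranks,
#'   `rank_sum`) and `selected_cost`.
#' @export
select_cost <- function(blocks, costs = cost_grid(), gamma = 1.0,
                        n_realizations = 20L, seed = 1L,
                        rule = c("rank_sum", "similarity_first",
                                 "stability_first")) {
  rule <- match.arg(rule)
  if (!"cm" %in% names(blocks)) blocks <- compute_connectivity(blocks)
  sw <- smallworld_feasible_costs(blocks, costs, n_realizations, seed)
  feas <- sw$cost[sw$feasible]
  if (length(feas) == 0L) {
    abort(paste("No cost satisfies the small-world criterion;",
                "widen or refine the cost grid."))
  }
  sim <- degree_similarity_score(blocks, feas)
  stab <- community_stability_score(blocks, feas, gamma)
  crit <- dplyr::left_join(sim, stab, by = "cost")
  crit$rank_similarity <- rank(-crit$similarity, ties.method = "min")
  crit$rank_stability <- rank(crit$stability_sd, ties.method = "min")
  crit$rank_sum <- crit$rank_similarity + crit$rank_stability

  selected <- switch(rule,
    rank_sum = crit$cost[order(crit$rank_sum, crit$cost)][1L],
    similarity_first = crit$cost[order(crit$rank_similarity,
                                       crit$rank_stability, crit$cost)][1L],
    stability_first = crit$cost[order(crit$rank_stability,
                                      crit$rank_similarity, crit$cost)][1L])

  table <- dplyr::left_join(sw, crit, by = "cost")
  structure(list(table = table, selected_cost = selected, rule = rule,
                 gamma = gamma, n_realizations = as.integer(n_realizations),
                 seed = as.integer(seed)),
            class = "cost_selection")
}

#' @export
print.cost_selection <- function(x, ...) {
  cat(sprintf("<cost_selection> selected cost = %g (%s rule, %d/%d feasible)\n",
              x$selected_cost, x$rule, sum(x$table$feasible), nrow(x$table)))
  invisible(x)
}

#' @rdname select_cost
#' @param x A `cost_selection`.
#' @param ... Unused.
#' @method tidy cost_selection
#' @export
tidy.cost_selection <- function(x, ...) x$table
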