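#' Construct a directed acyclic graph
#'
#' @param nodes Character vector of variable names.
#' @param arcs Data frame with columns `parent` and `child` (zero rows
#'   allowed). Arcs must reference declared nodes and leave the graph acyclic.
#' @return An object of class `vdt_dag` with fields `nodes` and `arcs`.
#' @export
dag <- function(nodes, arcs = tibble::tibble(parent = character(),
                                             child = character())) {
  arcs <- tibble::as_tibble(arcs)[c("parent", "child")]
  bad <- setdiff(c(arcs$parent, arcs$child), nodes)
  if (length(bad) > 0) {
    abort(paste0("arcs reference undeclared node(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
  g <- structure(list(nodes = nodes, arcs = arcs), class = "vdt_dag")
  if (is.null(topological_order(g))) {
    abort("arcs contain a directed cycle")
  }
  g
}

# Kahn topological sort; NULL if cyclic.
topological_order <- function(g) {
  nodes <- g$nodes
  indeg <- setNames(integer(length(nodes)), nodes)
  for (ch in g$arcs$child) indeg[ch] <- indeg[ch] + 1L
  order <- character(0)
  ready <- sort(names(indeg)[indeg == 0])
  arcs <- g$arcs
  while (length(ready) > 0) {
    v <- ready[[1]]
    ready <- ready[-1]
    order <- c(order, v)
    out <- arcs$child[arcs$parent == v]
    arcs <- arcs[arcs$parent != v, ]
    for (ch in out) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0) ready <- sort(c(ready, ch))
    }
  }
  if (length(order) == length(nodes)) order else NULL
}

dag_parents <- function(g, node) {
  sort(g$arcs$parent[g$arcs$child == node])
}

#' Construct a discrete Bayesian network
#'
#' A Bayesian network is the triplet of variables, a directed acyclic graph,
#' and one conditional probability table (CPT) per node; the joint
#' distribution factorises as the product of each node's CPT given its
#' parents.
#'
#' @param variables Named list: for each node, its ordered character vector of
#'   state labels (>= 2 states, used for deterministic tie-breaking).
#' @param graph A `vdt_dag` over exactly those nodes.
#' @param cpts Named list with one entry per node, each created by [cpt()];
#'   CPT parents must match the graph parents exactly.
#' @return An object of class `vdt_bn`.
#' @export
bayesian_network <- function(variables, graph, cpts) {
  if (!setequal(names(variables), graph$nodes)) {
    abort("`variables` must cover exactly the graph nodes")
  }
  for (v in graph$nodes) {
    st <- variables[[v]]
    if (length(st) < 2 || anyDuplicated(st) > 0) {
      abort(paste0("variable '", v, "': needs >= 2 unique state labels"))
    }
    if (is.null(cpts[[v]])) abort(paste0("missing CPT for node '", v, "'"))
    if (!identical(sort(cpts[[v]]$parents), dag_parents(graph, v))) {
      abort(paste0("CPT parents for '", v, "' do not match graph parents"))
    }
    dn <- dimnames(cpts[[v]]$prob)
    if (!identical(dn[[1]], st)) {
      abort(paste0("CPT for '", v, "' does not enumerate its declared states"))
    }
    sums <- if (length(dim(cpts[[v]]$prob)) == 1) sum(cpts[[v]]$prob)
            else apply(cpts[[v]]$prob, seq_along(dim(cpts[[v]]$prob))[-1], sum)
    if (any(abs(sums - 1) > 1e-9)) {
      abort(paste0("CPT for '", v, "' has a row not summing to 1"))
    }
  }
  structure(list(variables = variables, graph = graph, cpts = cpts),
            class = "vdt_bn")
}

#' Construct a conditional probability table
#'
#' @param child Child variable name.
#' @param parents Character vector of parent names (possibly empty).
#' @param prob Numeric array of P(child state | parent states): first
#'   dimension indexes child states, remaining dimensions the parents in
#'   `parents` order; full dimnames required. Every child-state distribution
#'   must sum to 1 (tolerance 1e-9).
#' @return A list of class `vdt_cpt`.
#' @export
cpt <- function(child, parents, prob) {
  if (is.null(dim(prob))) {
    prob <- array(prob, dim = length(prob),
                  dimnames = stats::setNames(list(names(prob)), child))
  }
  dn <- dimnames(prob)
  if (is.null(dn) || is.null(names(dn)) ||
      !identical(names(dn), c(child, parents))) {
    abort("`prob` must carry named dimnames: child first, then parents in order")
  }
  structure(list(child = child, parents = parents, prob = prob),
            class = "vdt_cpt")
}

# ---- factors for exact inference -------------------------------------------

new_factor <- function(vars, arr) list(vars = vars, arr = arr)

factor_states <- function(f) {
  if (length(f$vars) == 0) return(list())
  stats::setNames(dimnames(f$arr), f$vars)
}

factor_product <- function(f1, f2) {
  if (length(f1$vars) == 0) return(new_factor(f2$vars, f2$arr * as.numeric(f1$arr)))
  if (length(f2$vars) == 0) return(new_factor(f1$vars, f1$arr * as.numeric(f2$arr)))
  states <- utils::modifyList(factor_states(f1), factor_states(f2))
  grid <- do.call(expand.grid,
                  c(lapply(states, seq_along),
                    list(KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)))
  v1 <- f1$arr[as.matrix(grid[, f1$vars, drop = FALSE])]
  v2 <- f2$arr[as.matrix(grid[, f2$vars, drop = FALSE])]
  arr <- array(v1 * v2, dim = lengths(states), dimnames = states)
  new_factor(names(states), arr)
}

factor_marginalize <- function(f, var) {
  k <- match(var, f$vars)
  if (is.na(k)) return(f)
  if (length(f$vars) == 1) {
    return(new_factor(character(0), array(sum(f$arr))))
  }
  keep <- seq_along(f$vars)[-k]
  arr <- apply(f$arr, keep, sum)
  states <- factor_states(f)[keep]
  arr <- array(arr, dim = lengths(states), dimnames = states)
  new_factor(f$vars[keep], arr)
}

factor_reduce <- function(f, var, state) {
  k <- match(var, f$vars)
  if (is.na(k)) return(f)
  idx <- rep(list(quote(expr = )), length(f$vars))
  idx[[k]] <- state
  arr <- do.call(`[`, c(list(f$arr), idx, list(drop = FALSE)))
  if (length(f$vars) == 1) {
    return(new_factor(character(0), array(as.numeric(arr))))
  }
  states <- factor_states(f)[-k]
  arr <- array(arr, dim = lengths(states), dimnames = states)
  new_factor(f$vars[-k], arr)
}

# Variable elimination with a min-degree order (ties broken alphabetically).
eliminate <- function(factors, hidden) {
  hidden <- sort(hidden)
  while (length(hidden) > 0) {
    degree <- purrr::map_int(hidden, function(v) {
      nb <- unique(unlist(purrr::map(factors,
                                     ~ if (v %in% .x$vars) .x$vars else NULL)))
      length(setdiff(nb, v))
    })
    v <- hidden[order(degree, hidden)][[1]]
    hidden <- setdiff(hidden, v)
    involved <- purrr::map_lgl(factors, ~ v %in% .x$vars)
    prod_f <- purrr::reduce(factors[involved], factor_product,
                            .init = new_factor(character(0), array(1)))
    factors <- c(factors[!involved], list(factor_marginalize(prod_f, v)))
  }
  factors
}

check_evidence <- function(bn, evidence) {
  if (is.null(evidence) || length(evidence) == 0) return(invisible(NULL))
  evidence <- unlist(evidence)
  bad <- setdiff(names(evidence), names(bn$variables))
  if (length(bad) > 0) {
    abort(paste0("evidence on unknown variable(s): ", paste(bad, collapse = ", ")))
  }
  for (v in names(evidence)) {
    if (!evidence[[v]] %in% bn$variables[[v]]) {
      abort(paste0("evidence state '", evidence[[v]],
                   "' is not a state of variable '", v, "'"))
    }
  }
  invisible(NULL)
}

#' Exact posterior distribution of one variable
#'
#' Computes the conditional distribution of `query` given `evidence` by
#' variable elimination (exact; networks here are small). States are returned
#' in the variable's declared order.
#'
#' @param bn A `vdt_bn`.
#' @param query Variable name; must not appear in the evidence.
#' @param evidence Named character vector or list mapping observed variables
#'   to states; `NULL` for the prior marginal.
#' @return Named numeric vector over the query's states, summing to 1.
#' @export
posterior <- function(bn, query, evidence = NULL) {
  posterior_impl(bn, query, evidence)
}

posterior_impl <- function(bn, query, evidence = NULL, extra_factors = list()) {
  if (!query %in% names(bn$variables)) {
    abort(paste0("unknown query variable '", query, "'"))
  }
  evidence <- if (is.null(evidence)) character(0) else unlist(evidence)
  if (query %in% names(evidence)) {
    abort("`query` must not appear in the evidence")
  }
  check_evidence(bn, evidence)
  factors <- c(purrr::map(bn$cpts, ~ new_factor(c(.x$child, .x$parents), .x$prob)),
               extra_factors)
  for (v in names(evidence)) {
    factors <- purrr::map(factors, factor_reduce, var = v,
                          state = evidence[[v]])
  }
  hidden <- setdiff(names(bn$variables), c(query, names(evidence)))
  factors <- eliminate(factors, hidden)
  res <- purrr::reduce(factors, factor_product,
                       .init = new_factor(character(0), array(1)))
  probs <- as.numeric(res$arr)
  if (length(res$vars) == 0) {
    abort("internal error: query eliminated")
  }
  names(probs) <- dimnames(res$arr)[[1]]
  total <- sum(probs)
  if (total <= 0) {
    abort("evidence has probability zero under the network")
  }
  (probs / total)[bn$variables[[query]]]
}

#' Joint probability of a full assignment
#'
#' Evaluates the factorised joint: the product over nodes of the CPT entry
#' selected by the assignment.
#'
#' @param bn A `vdt_bn`.
#' @param assignment Named character vector/list giving a state for every
#'   variable in the network.
#' @return A single probability.
#' @export
joint_probability <- function(bn, assignment) {
  assignment <- unlist(assignment)
  missing <- setdiff(names(bn$variables), names(assignment))
  if (length(missing) > 0) {
    abort(paste0("assignment must cover every variable; missing: ",
                 paste(missing, collapse = ", ")))
  }
  check_evidence(bn, assignment)
  prod(purrr::map_dbl(bn$cpts, function(ct) {
    idx <- matrix(assignment[c(ct$child, ct$parents)], nrow = 1)
    as.numeric(ct$prob[idx])
  }))
}

# ---- structure learning ----------------------------------------------------

#' Conditional mutual information between two categorical variables
#'
#' Empirical CMI(x; y | given) in nats, estimated from the record
#' frequencies. Non-negative and symmetric in `x` and `y`.
#'
#' @param records Data frame of categorical records.
#' @param x,y Column names of the two variables.
#' @param given Column name of the conditioning variable.
#' @return A single non-negative number (nats).
#' @export
conditional_mutual_information <- function(records, x, y, given) {
  tab <- table(records[[given]], records[[x]], records[[y]])
  p <- tab / sum(tab)
  pt <- apply(p, 1, sum)
  ptx <- apply(p, c(1, 2), sum)
  pty <- apply(p, c(1, 3), sum)
  total <- 0
  for (t in seq_len(dim(p)[1])) {
    for (i in seq_len(dim(p)[2])) {
      for (j in seq_len(dim(p)[3])) {
        pv <- p[t, i, j]
        if (pv > 0) {
          total <- total + pv * log(pv * pt[t] / (ptx[t, i] * pty[t, j]))
        }
      }
    }
  }
  max(total, 0)
}

#' Learn an augmented-naive-Bayes structure
#'
#' Builds the classifier DAG used for disorder inference: the naive star
#' (target -> every feature) enriched with feature-to-feature arcs. Candidate
#' feature pairs are weighted by conditional mutual information given the
#' target; pairs at or below `cmi_threshold` are pruned, a maximum-weight
#' spanning forest is extracted from the survivors (Kruskal; ties broken by
#' lexicographic pair order), and each tree is directed away from its
#' lexicographically smallest member, so every feature gains at most one
#' feature parent.
#'
#' @param records Data frame of categorical records including the target.
#' @param target Name of the class column (the common parent).
#' @param cmi_threshold Non-negative CMI pruning threshold in nats.
#' @return A `vdt_dag` whose arcs are the naive star plus the augmentation
#'   forest.
#' @export
learn_abn_structure <- function(records, target = "disorder",
                                cmi_threshold = 0.01) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("`records` must be a non-empty data frame")
  }
  if (!target %in% names(records)) {
    abort(paste0("target variable '", target, "' not present in records"))
  }
  if (cmi_threshold < 0) abort("`cmi_threshold` must be non-negative")
  features <- setdiff(names(records), target)
  star <- tibble::tibble(parent = target, child = features)

  pairs <- utils::combn(sort(features), 2, simplify = FALSE)
  edges <- purrr::map(pairs, function(pr) {
    tibble::tibble(i = pr[[1]], j = pr[[2]],
                   weight = conditional_mutual_information(records, pr[[1]],
                                                           pr[[2]], target))
  }) %>%
    bind_rows() %>%
    filter(.data$weight > cmi_threshold) %>%
    arrange(dplyr::desc(.data$weight), .data$i, .data$j)

  # Kruskal maximum-weight spanning forest via union-find.
  parent_of <- stats::setNames(features, features)
  find_root <- function(v) {
    while (parent_of[[v]] != v) v <- parent_of[[v]]
    v
  }
  kept <- list()
  if (nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      ri <- find_root(edges$i[[r]])
      rj <- find_root(edges$j[[r]])
      if (ri != rj) {
        parent_of[[ri]] <- rj
        kept[[length(kept) + 1]] <- c(edges$i[[r]], edges$j[[r]])
      }
    }
  }

  aug <- tibble::tibble(parent = character(0), child = character(0))
  if (length(kept) > 0) {
    adj <- purrr::map(stats::setNames(features, features), ~ character(0))
    for (e in kept) {
      adj[[e[[1]]]] <- c(adj[[e[[1]]]], e[[2]])
      adj[[e[[2]]]] <- c(adj[[e[[2]]]], e[[1]])
    }
    comp_nodes <- unique(unlist(kept))
    visited <- character(0)
    for (root in sort(comp_nodes)) {
      if (root %in% visited) next
      queue <- root
      visited <- c(visited, root)
      while (length(queue) > 0) {
        v <- queue[[1]]
        queue <- queue[-1]
        for (w in sort(adj[[v]])) {
          if (!w %in% visited) {
            aug <- bind_rows(aug, tibble::tibble(parent = v, child = w))
            visited <- c(visited, w)
            queue <- c(queue, w)
          }
        }
      }
    }
  }
  dag(nodes = c(target, features), arcs = bind_rows(star, aug))
}

# ---- parameter estimation --------------------------------------------------

#' Declared state sets for the exam-record variables
#'
#' @return Named list of ordered state vectors for the seven clinical
#'   attributes plus `disorder`.
#' @export
exam_variable_states <- function() {
  c(exam_attribute_states(), list(disorder = disorder_classes()))
}

#' Fit conditional probability tables by maximum likelihood
#'
#' Estimates each node's CPT from record frequencies:
#' `(count + smoothing) / (row total + smoothing * n_states)`. With
#' `smoothing = 0`, a parent-state combination never observed yields a uniform
#' row (documented fallback).
#'
#' @param graph A `vdt_dag`.
#' @param records Data frame covering every graph node.
#' @param smoothing Non-negative additive smoothing constant (default 0, the
#'   plain maximum-likelihood frequency estimator).
#' @param states Optional named list of declared state sets. By default, exam
#'   schema variables use [exam_variable_states()] and any other variable uses
#'   the sorted unique values observed in `records`. Record values outside a
#'   declared state set are an error.
#' @return A `vdt_bn`.
#' @export
fit_mle <- function(graph, records, smoothing = 0, states = NULL) {
  if (smoothing < 0) abort("`smoothing` must be non-negative")
  missing <- setdiff(graph$nodes, names(records))
  if (length(missing) > 0) {
    abort(paste0("records do not cover graph node(s): ",
                 paste(missing, collapse = ", ")))
  }
  exam_states <- exam_variable_states()
  variables <- purrr::map(stats::setNames(graph$nodes, graph$nodes), function(v) {
    if (!is.null(states[[v]])) states[[v]]
    else if (v %in% names(exam_states)) exam_states[[v]]
    else sort(unique(records[[v]]))
  })
  for (v in graph$nodes) {
    bad <- setdiff(unique(records[[v]]), variables[[v]])
    if (length(bad) > 0) {
      abort(paste0("variable '", v, "': record state(s) outside declared set: ",
                   paste(bad, collapse = ", ")))
    }
  }
  cpts <- purrr::map(stats::setNames(graph$nodes, graph$nodes), function(v) {
    parents <- dag_parents(graph, v)
    fs <- purrr::map(c(v, parents), ~ factor(records[[.x]],
                                             levels = variables[[.x]]))
    counts <- table(fs)
    names(dimnames(counts)) <- c(v, parents)
    k <- length(variables[[v]])
    num <- counts + smoothing
    if (length(parents) == 0) {
      tot <- sum(num)
      prob <- if (tot > 0) num / tot else array(1 / k, dim = k)
      prob <- array(as.numeric(prob), dim = k,
                    dimnames = stats::setNames(list(variables[[v]]), v))
    } else {
      pdims <- seq_along(dim(counts))[-1]
      tot <- apply(num, pdims, sum)
      prob <- sweep(num, pdims, tot, "/")
      # unobserved parent combination with smoothing 0: uniform fallback
      uniform <- sweep(array(0, dim(prob)), pdims, tot == 0, "+") / k
      prob[is.nan(prob)] <- 0
      prob <- prob + uniform
      dn <- purrr::map(c(v, parents), ~ variables[[.x]])
      prob <- array(as.numeric(prob), dim = dim(counts),
                    dimnames = stats::setNames(dn, c(v, parents)))
    }
    cpt(v, parents, prob)
  })
  bayesian_network(variables, graph, cpts)
}

# ---- naive network from a population spec ----------------------------------

#' Naive Bayesian network with parameters taken from a population spec
#'
#' Builds the star-shaped network disorder -> each attribute whose CPTs are
#' the spec's class prior and class-conditional risk-state probabilities
#' directly (no data, no estimation). Diagnostic inference on this network
#' returns the spec's conditionals exactly.
#'
#' @param spec A `vdt_population_spec`.
#' @return A `vdt_bn`.
#' @export
naive_bn_from_spec <- function(spec) {
  validate_population_spec(spec)
  attrs <- names(spec$attribute_states)
  cls <- disorder_classes()
  g <- dag(nodes = c("disorder", attrs),
           arcs = tibble::tibble(parent = "disorder", child = attrs))
  variables <- c(list(disorder = cls), spec$attribute_states)
  cpts <- list(disorder = cpt("disorder", character(0),
                              array(spec$class_prior[cls], dim = length(cls),
                                    dimnames = list(disorder = cls))))
  for (a in attrs) {
    pr <- spec$conditionals[cls, a]
    m <- rbind(pr, 1 - pr)
    cpts[[a]] <- cpt(a, "disorder",
                     array(m, dim = c(2, length(cls)),
                           dimnames = stats::setNames(
                             list(spec$attribute_states[[a]], cls),
                             c(a, "disorder"))))
  }
  bayesian_network(variables, g, cpts)
}

# ---- applied inference -----------------------------------------------------

#' Diagnostic risk-factor profile of a disorder class
#'
#' Diagnostic reasoning from the disorder back to each clinical attribute:
#' one posterior call per attribute conditioning on
#' `disorder = disorder_state`, reporting the probability of the attribute's
#' risk state.
#'
#' @param bn A `vdt_bn` containing a `disorder` node and exam attributes.
#' @param disorder_state One of [disorder_classes()] (or any declared state of
#'   the network's disorder variable).
#' @return Tibble with columns `attribute`, `risk_state`, `probability`.
#' @export
diagnostic_profile <- function(bn, disorder_state) {
  if (!"disorder" %in% names(bn$variables)) {
    abort("network has no 'disorder' variable")
  }
  if (!disorder_state %in% bn$variables$disorder) {
    abort(paste0("unknown disorder state '", disorder_state, "'"))
  }
  attrs <- intersect(names(exam_attribute_states()), names(bn$variables))
  purrr::map(attrs, function(a) {
    post <- posterior(bn, a, c(disorder = disorder_state))
    risk <- bn$variables[[a]][[1]]
    tibble::tibble(attribute = a, risk_state = risk,
                   probability = unname(post[[risk]]))
  }) %>% bind_rows()
}

#' Classify a record's most probable disorder
#'
#' Predictive reasoning: the maximum-a-posteriori state of the target given
#' attribute evidence. Posterior ties are broken by the target's declared
#' state order.
#'
#' @param bn A `vdt_bn`.
#' @param evidence Named character vector of observed attribute states (must
#'   not include the target).
#' @param target Target variable name (default `"disorder"`).
#' @return The winning state label (length-1 character).
#' @export
classify <- function(bn, evidence, target = "disorder") {
  post <- posterior(bn, target, evidence)
  names(post)[[which.max(post)]]
}

#' One-way sensitivity of a posterior to a marginal perturbation
#'
#' Shifts the marginal probability of `source_state` by `delta` (the other
#' states of the source are rescaled proportionally), recomputes the target
#' posterior under the perturbed distribution, and returns the signed change
#' in P(`target = target_state`).
#'
#' @param bn A `vdt_bn`.
#' @param source,source_state Variable and state being perturbed.
#' @param delta Signed perturbation; the perturbed marginal must stay in
#'   `[0, 1]`.
#' @param target,target_state Variable and state whose posterior change is
#'   measured.
#' @return Signed numeric change in the target-state probability.
#' @export
sensitivity <- function(bn, source, source_state, delta, target, target_state) {
  if (!source %in% names(bn$variables) || !target %in% names(bn$variables)) {
    abort("`source` and `target` must be network variables")
  }
  if (!source_state %in% bn$variables[[source]]) {
    abort(paste0("'", source_state, "' is not a state of '", source, "'"))
  }
  if (!target_state %in% bn$variables[[target]]) {
    abort(paste0("'", target_state, "' is not a state of '", target, "'"))
  }
  if (delta == 0) return(0)
  marg <- posterior(bn, source)
  p <- unname(marg[[source_state]])
  p_new <- p + delta
  if (p_new < 0 || p_new > 1) {
    abort("perturbed probability falls outside [0, 1]")
  }
  if (p <= 0 || p >= 1) {
    abort("source-state marginal is degenerate (0 or 1); cannot renormalize")
  }
  w <- stats::setNames(rep((1 - p_new) / (1 - p), length(marg)), names(marg))
  w[[source_state]] <- p_new / p
  weight_factor <- new_factor(source,
                              array(w, dim = length(w),
                                    dimnames = stats::setNames(
                                      list(names(marg)), source)))
  base <- posterior(bn, target)[[target_state]]
  pert <- posterior_impl(bn, target,
                         extra_factors = list(weight_factor))[[target_state]]
  unname(pert - base)
}

# ---- serialization & methods -----------------------------------------------

#' Read or write a Bayesian network as JSON
#'
#' @param bn A `vdt_bn`.
#' @param path File path.
#' @return `read_network()` returns a `vdt_bn`; `write_network()` returns
#'   `path` invisibly.
#' @export
write_network <- function(bn, path) {
  x <- list(
    variables = purrr::imap(bn$variables, ~ list(name = .y, states = .x)),
    arcs = bn$graph$arcs,
    cpts = purrr::map(bn$cpts, function(ct) {
      list(child = ct$child, parents = ct$parents,
           dim = dim(ct$prob),
           values = as.numeric(ct$prob))
    })
  )
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  variables <- purrr::map(x$variables, ~ unlist(.x$states))
  arcs <- tibble::as_tibble(x$arcs)
  if (nrow(arcs) == 0) arcs <- tibble::tibble(parent = character(0),
                                              child = character(0))
  g <- dag(names(variables), arcs)
  cpts <- purrr::imap(x$cpts, function(ct, nm) {
    parents <- unlist(ct$parents) %||% character(0)
    dn <- purrr::map(c(ct$child, parents), ~ variables[[.x]])
    prob <- array(unlist(ct$values), dim = unlist(ct$dim),
                  dimnames = stats::setNames(dn, c(ct$child, parents)))
    cpt(ct$child, parents, prob)
  })
  bayesian_network(variables, g, cpts[names(variables)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.vdt_bn <- function(x, ...) {
  cat("<vdt_bn> discrete Bayesian network\n")
  cat("  nodes:", length(x$variables), "  arcs:", nrow(x$graph$arcs), "\n")
  cat("  variables:", paste(names(x$variables), collapse = ", "), "\n")
  invisible(x)
}

#' Tidy a fitted Bayesian network into CPT rows
#'
#' @param x A `vdt_bn`.
#' @param ... Unused.
#' @return Tibble with one row per CPT entry: `node`, `state`,
#'   `parent_config` (semicolon-joined `parent=state` pairs, `NA` for roots)
#'   and `probability`.
#' @export
tidy.vdt_bn <- function(x, ...) {
  purrr::map(x$cpts, function(ct) {
    dn <- dimnames(ct$prob)
    grid <- do.call(expand.grid, c(dn, list(KEEP.OUT.ATTRS = FALSE,
                                            stringsAsFactors = FALSE)))
    cfg <- if (length(ct$parents) == 0) NA_character_ else {
      apply(grid[, ct$parents, drop = FALSE], 1, function(r) {
        paste(paste0(ct$parents, "=", r), collapse = ";")
      })
    }
    tibble::tibble(node = ct$child, state = grid[[ct$child]],
                   parent_config = cfg,
                   probability = as.numeric(ct$prob))
  }) %>% bind_rows()
}

#' Summarise a Bayesian network
#'
#' @param x A `vdt_bn`.
#' @param ... Unused.
#' @return One-row tibble: `n_nodes`, `n_arcs`, `n_augmentation_arcs` (arcs
#'   not leaving the disorder node, `NA` when no disorder node exists) and
#'   `n_parameters` (free CPT entries).
#' @method glance vdt_bn
#' @export
glance.vdt_bn <- function(x, ...) {
  arcs <- x$graph$arcs
  n_aug <- if ("disorder" %in% names(x$variables)) {
    sum(arcs$parent != "disorder")
  } else NA_integer_
  n_par <- sum(purrr::map_dbl(x$cpts, function(ct) {
    d <- dim(ct$prob)
    (d[1] - 1) * prod(d[-1])
  }))
  tibble::tibble(n_nodes = length(x$variables), n_arcs = nrow(arcs),
                 n_augmentation_arcs = n_aug, n_parameters = n_par)
}

#' Plot a Bayesian network's graph
#'
#' Simple circular-layout arc diagram of the DAG.
#'
#' @param object A `vdt_bn`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot vdt_bn
#' @export
autoplot.vdt_bn <- function(object, ...) {
  nodes <- names(object$variables)
  k <- length(nodes)
  theta <- 2 * pi * (seq_len(k) - 1) / k
  layout <- tibble::tibble(node = nodes, x = cos(theta), y = sin(theta))
  arcs <- object$graph$arcs %>%
    left_join(layout, by = c(parent = "node")) %>%
    left_join(layout, by = c(child = "node"), suffix = c("", "end"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = arcs,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      arrow = ggplot2::arrow(length = ggplot2::unit(0.15, "inches")),
      colour = "grey40") +
    ggplot2::geom_label(data = layout,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     label = .data$node)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
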