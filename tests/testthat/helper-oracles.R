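# Independent oracles used to cross-check the package's inference paths.
# Nothing here calls the package's variable-elimination, CMI or classifier
# code; lookups into the bn object read its stored CPT arrays directly.

# Full-enumeration posterior: sum the factorised joint over every complete
# assignment compatible with the evidence.
enum_posterior <- function(bn, query, evidence = NULL) {
  states <- bn$variables
  grid <- do.call(expand.grid, c(states, list(KEEP.OUT.ATTRS = FALSE,
                                              stringsAsFactors = FALSE)))
  if (!is.null(evidence)) {
    for (v in names(evidence)) grid <- grid[grid[[v]] == evidence[[v]], ]
  }
  joint <- vapply(seq_len(nrow(grid)), function(r) {
    prod(vapply(names(states), function(v) {
      ct <- bn$cpts[[v]]
      idx <- matrix(unlist(grid[r, c(ct$child, ct$parents)]), nrow = 1)
      as.numeric(ct$prob[idx])
    }, numeric(1)))
  }, numeric(1))
  probs <- vapply(states[[query]], function(s) sum(joint[grid[[query]] == s]),
                  numeric(1))
  probs / sum(probs)
}

# Brute-force conditional mutual information from a 3-way contingency table.
enum_cmi <- function(records, x, y, given) {
  tab <- table(records[[given]], records[[x]], records[[y]])
  p <- tab / sum(tab)
  total <- 0
  for (t in dimnames(p)[[1]]) for (i in dimnames(p)[[2]]) {
    for (j in dimnames(p)[[3]]) {
      pv <- p[t, i, j]
      if (pv > 0) {
        total <- total + pv * log(pv * sum(p[t, , ]) /
                                    (sum(p[t, i, ]) * sum(p[t, , j])))
      }
    }
  }
  total
}

# Independent naive-Bayes classifier from raw frequency counts.
naive_bayes_oracle <- function(records, evidence, target = "disorder",
                               classes = disorder_classes()) {
  scores <- vapply(classes, function(cl) {
    sub <- records[records[[target]] == cl, ]
    prior <- nrow(sub) / nrow(records)
    lik <- prod(vapply(names(evidence), function(a) {
      mean(sub[[a]] == evidence[[a]])
    }, numeric(1)))
    prior * lik
  }, numeric(1))
  classes[[which.max(scores)]]
}

# Random binary-node network on <= max_nodes nodes with Dirichlet-ish CPTs.
random_binary_bn <- function(n_nodes) {
  nodes <- paste0("v", seq_len(n_nodes))
  arcs <- list()
  for (i in seq_len(n_nodes)) {
    for (j in seq_len(n_nodes)) {
      if (i < j && runif(1) < 0.4) {
        arcs[[length(arcs) + 1]] <- c(nodes[[i]], nodes[[j]])
      }
    }
  }
  arcs <- if (length(arcs) == 0) {
    tibble::tibble(parent = character(0), child = character(0))
  } else {
    tibble::tibble(parent = vapply(arcs, `[[`, "", 1),
                   child = vapply(arcs, `[[`, "", 2))
  }
  g <- dag(nodes, arcs)
  variables <- stats::setNames(rep(list(c("s0", "s1")), n_nodes), nodes)
  cpts <- lapply(nodes, function(v) {
    parents <- sort(arcs$parent[arcs$child == v])
    n_combo <- 2^length(parents)
    p1 <- runif(n_combo, 0.05, 0.95)
    m <- rbind(p1, 1 - p1)
    dn <- c(list(c("s0", "s1")), rep(list(c("s0", "s1")), length(parents)))
    prob <- array(m, dim = c(2, rep(2, length(parents))),
                  dimnames = stats::setNames(dn, c(v, parents)))
    cpt(v, parents, prob)
  })
  bayesian_network(variables, g, stats::setNames(cpts, nodes))
}
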