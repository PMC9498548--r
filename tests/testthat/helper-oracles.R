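# Independent oracles and generators shared across tests.

# All permutations of 1..m as a list of integer vectors.
perms_of <- function(m) {
  if (m == 0L) return(list(integer()))
  if (m == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(m)) {
    for (p in perms_of(m - 1L)) {
      rest <- seq_len(m)[-i]
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# Brute-force simple-cycle enumeration, independent of the package's DFS:
# for every node subset, test every rotation-canonical ordering (smallest
# node first) for being a directed cycle in the adjacency matrix.
# Returns sorted canonical keys "n1|n2|...".
brute_force_cycles <- function(diagram, max_len = length(diagram$nodes)) {
  nodes <- sort(diagram$nodes)
  n <- length(nodes)
  if (n < 2L) return(character())
  adj <- matrix(FALSE, n, n, dimnames = list(nodes, nodes))
  if (nrow(diagram$edges)) {
    adj[cbind(diagram$edges$src, diagram$edges$dst)] <- TRUE
  }
  out <- character()
  for (k in 2:min(max_len, n)) {
    combs <- utils::combn(n, k, simplify = FALSE)
    perms <- perms_of(k - 1L)
    for (cmb in combs) {
      first <- cmb[1L]
      rest <- cmb[-1L]
      for (p in perms) {
        cyc <- c(first, if (k > 1L) rest[p])
        nxt <- c(cyc[-1L], cyc[1L])
        if (all(adj[cbind(cyc, nxt)])) {
          out <- c(out, paste(nodes[cyc], collapse = "|"))
        }
      }
    }
  }
  sort(out)
}

cycle_keys <- function(loops) {
  sort(vapply(loops, function(l) paste(l$cycle, collapse = "|"), ""))
}

# Random signed digraph on n nodes with edge probability p.
random_diagram <- function(n, p = 0.3) {
  nodes <- paste0("N", seq_len(n))
  edges <- list()
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && stats::runif(1) < p) {
        edges[[length(edges) + 1L]] <- signed_edge(
          nodes[i], nodes[j], sample(c(-1L, 1L), 1L))
      }
    }
  }
  causal_diagram(edges)
}

# Single-stock linear decay model: S' = -(r/100) S, S(0) = s0.
decay_model <- function(s0 = 1000, r = 10) {
  sd_model(
    stocks = list(sd_stock("S", s0)),
    flows = list(sd_flow("decay", "S", BOUNDARY, rate = "decay_rate")),
    auxiliaries = list(sd_aux("decay_rate", "S * r / 100", "persons/year")),
    parameters = c(r = r),
    name = "decay"
  )
}

# Closed two-stock chain A -> B with linear transfer.
chain_model <- function(a0 = 100, b0 = 0, r = 20) {
  sd_model(
    stocks = list(sd_stock("A", a0), sd_stock("B", b0)),
    flows = list(sd_flow("transfer", "A", "B", rate = "transfer_rate")),
    auxiliaries = list(sd_aux("transfer_rate", "A * r / 100")),
    parameters = c(r = r),
    name = "chain"
  )
}

# Coarse grid for fast scenario/sweep unit tests.
fast_config <- function() sim_config(2010, 2022, dt = 0.25)
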