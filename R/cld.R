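#' Signed causal edge
#'
#' A cause-to-effect arrow of a causal loop diagram. Sign +1 means effect
#' moves in the same direction as cause; -1 means the opposite direction.
#' The channel distinguishes disparity-driven influences from general
#' social influences (the red versus blue arrows of the diagram).
#'
#' @param src Cause variable name.
#' @param dst Effect variable name.
#' @param sign +1 or -1.
#' @param channel `"disparity"` or `"general"`.
#' @return An object of class `signed_edge`.
#' @export
signed_edge <- function(src, dst, sign, channel = "general") {
  stopifnot(is.character(src), length(src) == 1L, nzchar(src),
            is.character(dst), length(dst) == 1L, nzchar(dst))
  if (!sign %in% c(1, -1)) stop("sign must be +1 or -1", call. = FALSE)
  if (!channel %in% c("disparity", "general")) {
    stop("channel must be 'disparity' or 'general'", call. = FALSE)
  }
  structure(list(src = src, dst = dst, sign = as.integer(sign),
                 channel = channel),
            class = "signed_edge")
}

#' Build a causal loop diagram from signed edges
#'
#' Nodes are inferred from edge endpoints. At most one edge may exist per
#' ordered (src, dst) pair; declaring the same pair twice with conflicting
#' signs is an error (an exact duplicate is collapsed).
#'
#' @param edges List of [signed_edge()] objects.
#' @return An object of class `causal_diagram` with elements `nodes`
#'   (character vector) and `edges` (data frame with columns `src`, `dst`,
#'   `sign`, `channel`).
#' @export
#' @examples
#' d <- causal_diagram(list(
#'   signed_edge("Poverty", "Stress", +1),
#'   signed_edge("Stress", "Poverty", -1)
#' ))
#' enumerate_simple_cycles(d)
causal_diagram <- function(edges = list()) {
  for (e in edges) stopifnot(inherits(e, "signed_edge"))
  df <- if (length(edges)) {
    data.frame(src = vapply(edges, `[[`, "", "src"),
               dst = vapply(edges, `[[`, "", "dst"),
               sign = vapply(edges, function(e) e$sign, integer(1L)),
               channel = vapply(edges, `[[`, "", "channel"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(src = character(), dst = character(), sign = integer(),
               channel = character(), stringsAsFactors = FALSE)
  }
  key <- paste(df$src, df$dst, sep = "\r")
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      rows <- df[key == k, ]
      if (length(unique(rows$sign)) > 1L) {
        stop("conflicting signs for edge ", rows$src[1L], " -> ", rows$dst[1L],
             call. = FALSE)
      }
    }
    df <- df[!duplicated(key), ]
    rownames(df) <- NULL
  }
  structure(list(nodes = sort(unique(c(df$src, df$dst))), edges = df),
            class = "causal_diagram")
}

#' @export
print.causal_diagram <- function(x, ...) {
  cat("Causal loop diagram: ", length(x$nodes), " nodes, ",
      nrow(x$edges), " signed edges\n", sep = "")
  invisible(x)
}

## sign of edge src->dst, or NA if absent
edge_sign <- function(diagram, src, dst) {
  i <- which(diagram$edges$src == src & diagram$edges$dst == dst)
  if (length(i) != 1L) return(NA_integer_)
  diagram$edges$sign[i]
}

## rotate a cycle's node sequence so the lexicographically smallest node
## leads; used as the canonical representative (direction is preserved:
## reversal is a different cycle in a digraph)
canonical_rotation <- function(nodes) {
  i <- which(nodes == min(nodes))[1L]
  if (i == 1L) nodes else c(nodes[i:length(nodes)], nodes[seq_len(i - 1L)])
}

#' Enumerate simple directed cycles
#'
#' Finds every simple directed cycle of length between 2 and `max_len`,
#' each reported once up to rotation. Enumeration is a DFS rooted at each
#' node in sorted order, restricted to nodes not smaller than the root, so
#' each cycle is discovered exactly once at its smallest node.
#'
#' @param diagram A [causal_diagram()].
#' @param max_len Maximum cycle length (default: number of nodes, i.e. full
#'   enumeration). Must be >= 2.
#' @return List of `feedback_loop` objects, sorted by cycle length then by
#'   the canonical node sequence; each has `cycle` (nodes, first not
#'   repeated), `signs` (edge signs along the cycle) and `polarity`
#'   (`"reinforcing"` or `"balancing"`).
#' @export
enumerate_simple_cycles <- function(diagram, max_len = length(diagram$nodes)) {
  stopifnot(inherits(diagram, "causal_diagram"))
  if (length(diagram$nodes) == 0L) return(list())
  if (max_len < 2L) stop("max_len must be >= 2", call. = FALSE)
  nodes <- sort(diagram$nodes)
  adj <- split(diagram$edges$dst, factor(diagram$edges$src, levels = nodes))
  cycles <- list()
  for (root in nodes) {
    path <- character()
    dfs <- function(v) {
      path <<- c(path, v)
      for (w in sort(adj[[v]])) {
        if (w < root) next
        if (w == root) {
          if (length(path) >= 2L) cycles[[length(cycles) + 1L]] <<- path
        } else if (!(w %in% path) && length(path) < max_len) {
          dfs(w)
        }
      }
      path <<- path[-length(path)]
    }
    dfs(root)
  }
  loops <- lapply(cycles, function(cyc) make_loop(diagram, canonical_rotation(cyc)))
  if (length(loops) == 0L) return(loops)
  keys <- vapply(loops, function(l) paste(l$cycle, collapse = "\r"), "")
  lens <- lengths(lapply(loops, `[[`, "cycle"))
  loops[order(lens, keys)]
}

make_loop <- function(diagram, cycle, label = NA_character_) {
  nxt <- c(cycle[-1L], cycle[1L])
  signs <- mapply(edge_sign, src = cycle, dst = nxt,
                  MoreArgs = list(diagram = diagram))
  if (anyNA(signs)) {
    miss <- which(is.na(signs))[1L]
    stop("no edge ", cycle[miss], " -> ", nxt[miss], " in the diagram",
         call. = FALSE)
  }
  structure(list(cycle = cycle, signs = as.integer(signs),
                 polarity = loop_polarity(as.integer(signs)),
                 label = label),
            class = "feedback_loop")
}

#' @export
print.feedback_loop <- function(x, ...) {
  arrows <- paste0(" -", ifelse(x$signs == 1L, "(+)", "(-)"), "-> ")
  cat(if (!is.na(x$label)) paste0(x$label, ": "),
      paste0(x$cycle, arrows, collapse = ""), x$cycle[1L],
      "  [", x$polarity, "]\n", sep = "")
  invisible(x)
}

#' Polarity of a feedback loop
#'
#' A loop is reinforcing when the product of its edge signs is +1
#' (a perturbation travelling round the loop comes back amplified in the
#' same direction) and balancing when the product is -1 (the loop
#' self-corrects).
#'
#' @param signs Integer vector of edge signs (+1/-1) along the cycle, or a
#'   `feedback_loop` object.
#' @return `"reinforcing"` or `"balancing"`.
#' @export
loop_polarity <- function(signs) {
  if (inherits(signs, "feedback_loop")) signs <- signs$signs
  stopifnot(length(signs) >= 1L, all(signs %in% c(-1L, 1L)))
  if (prod(signs) > 0) "reinforcing" else "balancing"
}

#' Classify labelled feedback loops of a diagram
#'
#' Looks up each labelled cycle in the diagram, verifies every edge exists,
#' and reports its polarity plus summary counts.
#'
#' @param diagram A [causal_diagram()].
#' @param labels Named list: label -> character vector of cycle nodes (in
#'   order, first node not repeated at the end).
#' @return List with `table` (data frame: label, length, polarity, cycle)
#'   and `counts` (named vector with `reinforcing` and `balancing`).
#'   Errors, naming the label, if a labelled cycle uses an edge absent from
#'   the diagram.
#' @export
classify_labeled_loops <- function(diagram, labels) {
  stopifnot(inherits(diagram, "causal_diagram"), is.list(labels),
            !is.null(names(labels)))
  rows <- lapply(names(labels), function(lab) {
    loop <- tryCatch(make_loop(diagram, labels[[lab]], label = lab),
                     error = function(e) {
                       stop("loop '", lab, "': ", conditionMessage(e),
                            call. = FALSE)
                     })
    data.frame(label = lab, length = length(loop$cycle),
               polarity = loop$polarity,
               cycle = paste(loop$cycle, collapse = " -> "),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  counts <- c(reinforcing = sum(tab$polarity == "reinforcing"),
              balancing = sum(tab$polarity == "balancing"))
  list(table = tab, counts = counts)
}

#' Export a causal diagram to Graphviz DOT
#'
#' Edge colour encodes the channel (red = disparity, blue = general) and
#' the edge label carries the sign, matching the usual rendering of such
#' diagrams.
#'
#' @param diagram A [causal_diagram()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_dot <- function(diagram, path) {
  stopifnot(inherits(diagram, "causal_diagram"))
  lines <- c("digraph cld {", "  rankdir=LR;")
  for (n in diagram$nodes) {
    lines <- c(lines, sprintf("  \"%s\";", n))
  }
  for (i in seq_len(nrow(diagram$edges))) {
    e <- diagram$edges[i, ]
    lines <- c(lines, sprintf(
      "  \"%s\" -> \"%s\" [label=\"%s\", color=%s];",
      e$src, e$dst, if (e$sign > 0) "+" else "-",
      if (e$channel == "disparity") "red" else "blue"))
  }
  lines <- c(lines, "}")
  writeLines(lines, path)
  invisible(path)
}

#' Read a causal diagram from an edge-list file
#'
#' Plain-text format, one edge per line: `src, dst, sign, channel`
#' (comma-separated; sign is `+`/`-` or `+1`/`-1`; lines starting with `#`
#' are comments).
#'
#' @param path File path.
#' @return A [causal_diagram()].
#' @export
read_edge_list <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  edges <- lapply(lines, function(ln) {
    parts <- trimws(strsplit(ln, ",", fixed = TRUE)[[1L]])
    if (length(parts) != 4L) {
      stop("malformed edge record: '", ln, "'", call. = FALSE)
    }
    sgn <- switch(parts[3L], "+" = 1L, "+1" = 1L, "1" = 1L,
                  "-" = -1L, "-1" = -1L,
                  stop("bad sign '", parts[3L], "' in: ", ln, call. = FALSE))
    signed_edge(parts[1L], parts[2L], sgn, parts[4L])
  })
  causal_diagram(edges)
}

#' Write a causal diagram as an edge list
#'
#' @param diagram A [causal_diagram()].
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_edge_list <- function(diagram, path) {
  stopifnot(inherits(diagram, "causal_diagram"))
  lines <- c("# src, dst, sign, channel",
             sprintf("%s, %s, %s, %s", diagram$edges$src, diagram$edges$dst,
                     ifelse(diagram$edges$sign > 0, "+", "-"),
                     diagram$edges$channel))
  writeLines(lines, path)
  invisible(path)
}
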