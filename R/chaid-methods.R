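# Presentation methods for fitted CHAID trees.

node_percentages <- function(counts) {
  p <- 100 * counts / sum(counts)
  paste(sprintf("%s %d (%.0f%%)", names(counts), counts, p), collapse = ", ")
}

#' @describeIn chaid Tidy the node table: one row per node with class counts
#'   expanded into `n_<class>` columns and merged groups as a label string.
#' @param x A `chaid_tree`.
#' @param ... Unused.
#' @method tidy chaid_tree
#' @export
tidy.chaid_tree <- function(x, ...) {
  nodes <- x$nodes
  counts <- do.call(rbind, nodes$class_counts)
  colnames(counts) <- paste0("n_", x$classes)
  dplyr::bind_cols(
    nodes[c("node_id", "parent_id", "depth", "n")],
    as_tibble(counts),
    tibble(
      p_positive = counts[, 1] / nodes$n,
      split_variable = nodes$split_variable,
      groups = vapply(nodes$groups, function(g) {
        if (is.null(g)) NA_character_
        else paste(vapply(g, paste, character(1), collapse = "+"), collapse = " | ")
      }, character(1)),
      statistic = nodes$statistic, df = nodes$df, p_raw = nodes$p_raw,
      multiplier = nodes$multiplier, p_adj = nodes$p_adj,
      terminal = nodes$terminal
    )
  )
}

#' @describeIn chaid One-row model summary (node/leaf counts, depth, training
#'   misclassification of leaf majority prediction).
#' @method glance chaid_tree
#' @export
glance.chaid_tree <- function(x, ...) {
  nodes <- x$nodes
  leaves <- nodes[nodes$terminal, ]
  train_err <- sum(vapply(leaves$class_counts, function(cc) sum(cc) - max(cc),
                          numeric(1))) / x$n
  tibble(
    n = x$n,
    n_nodes = nrow(nodes),
    n_leaves = nrow(leaves),
    depth = max(nodes$depth),
    train_risk = train_err
  )
}

#' Render a CHAID tree as a text outline and DOT graph
#'
#' @param tree A fitted [chaid()] tree.
#' @return A list with `text` (character vector, one line per node, indented
#'   by depth) and `dot` (a Graphviz DOT digraph as a single string).
#' @export
render_tree <- function(tree) {
  nodes <- tree$nodes
  lines <- character(0)
  dot_nodes <- character(0)
  dot_edges <- character(0)
  emit <- function(id, indent, edge_label) {
    row <- nodes[nodes$node_id == id, ]
    counts <- row$class_counts[[1]]
    desc <- sprintf("node %d [n=%d] %s", id, row$n, node_percentages(counts))
    if (!row$terminal) {
      desc <- paste0(
        desc,
        sprintf("; split %s (chi2=%.2f, df=%d, adj p=%.3g, B=%g)",
                row$split_variable, row$statistic, row$df, row$p_adj,
                row$multiplier)
      )
    }
    prefix <- if (nzchar(edge_label)) paste0(edge_label, " -> ") else ""
    lines <<- c(lines, paste0(strrep("  ", indent), prefix, desc))
    label <- sprintf("Node %d\\nn=%d\\n%s", id, row$n,
                     gsub(", ", "\\\\n", node_percentages(counts)))
    if (!row$terminal) {
      label <- paste0(label, sprintf("\\n%s: chi2=%.2f, adj p=%.3g",
                                     row$split_variable, row$statistic,
                                     row$p_adj))
    }
    dot_nodes <<- c(dot_nodes, sprintf("  n%d [shape=box, label=\"%s\"];", id, label))
    if (!row$terminal) {
      kids <- nodes$node_id[!is.na(nodes$parent_id) & nodes$parent_id == id]
      groups <- row$groups[[1]]
      for (j in seq_along(kids)) {
        glab <- paste(groups[[j]], collapse = ",")
        dot_edges <<- c(dot_edges,
                        sprintf("  n%d -> n%d [label=\"%s\"];", id, kids[j], glab))
        emit(kids[j], indent + 1L, glab)
      }
    }
  }
  emit(0L, 0L, "")
  dot <- paste(c("digraph chaid_tree {", dot_nodes, dot_edges, "}"),
               collapse = "\n")
  list(text = lines, dot = dot)
}

#' @export
print.chaid_tree <- function(x, ...) {
  cat(sprintf("CHAID tree for `%s` (%d nodes, %d leaves, n=%d)\n",
              x$target, nrow(x$nodes), sum(x$nodes$terminal), x$n))
  writeLines(render_tree(x)$text)
  invisible(x)
}

#' @describeIn chaid Node-link diagram of the tree (nodes sized by sample
#'   count, labelled with class percentages and split statistics).
#' @param object A `chaid_tree`.
#' @method autoplot chaid_tree
#' @export
autoplot.chaid_tree <- function(object, ...) {
  nd <- tidy(object)
  # x-position: leaves evenly spaced, internal nodes centered over children
  pos <- setNames(rep(NA_real_, nrow(nd)), nd$node_id)
  leaf_ids <- nd$node_id[nd$terminal]
  pos[as.character(leaf_ids)] <- seq_along(leaf_ids)
  for (d in sort(unique(nd$depth), decreasing = TRUE)) {
    for (id in nd$node_id[nd$depth == d & !nd$terminal]) {
      kids <- nd$node_id[!is.na(nd$parent_id) & nd$parent_id == id]
      pos[as.character(id)] <- mean(pos[as.character(kids)])
    }
  }
  nd$x <- pos[as.character(nd$node_id)]
  nd$y <- -nd$depth
  edges <- nd[!is.na(nd$parent_id), ]
  parent_idx <- match(edges$parent_id, nd$node_id)
  edges$x_from <- nd$x[parent_idx]
  edges$y_from <- nd$y[parent_idx]
  nd$label <- sprintf("Node %d\nn=%d, %.0f%% %s", nd$node_id, nd$n,
                      100 * nd$p_positive, object$classes[1])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x_from, y = .data$y_from,
                   xend = .data$x, yend = .data$y),
      colour = "grey60"
    ) +
    ggplot2::geom_label(
      data = nd,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      size = 3
    ) +
    ggplot2::theme_void() +
    ggplot2::labs(title = sprintf("CHAID tree for %s", object$target))
}
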