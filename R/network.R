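## node naming convention "<enzyme>_<param>_<system>", e.g. LAP_spVmax_HA;
## anything else is treated as an environmental / community variable
parse_node_tags <- function(name) {
  parts <- strsplit(name, "_", fixed = TRUE)[[1L]]
  enzyme <- if (parts[1L] %in% c("LAP", "BG", "AG")) parts[1L] else NA_character_
  system <- if (parts[length(parts)] %in% c("HA", "LA")) parts[length(parts)] else NA_character_
  list(enzyme = enzyme, system = system)
}

#' Assemble an association network from LSA results
#'
#' Keeps results with `q_value <= q_threshold` and `|ls_score| >=
#' min_abs_ls` as edges of a signed, possibly time-delayed association
#' network. Edges with nonzero delay are directed from the leading variable
#' to the follower (positive delay means `var_x` precedes `var_y`);
#' contemporaneous edges (delay 0) are undirected. All variables appearing
#' in `results` become nodes, whether or not they retain edges.
#'
#' @param results Tibble from [lsa_all_pairs()] (must carry `q_value`).
#' @param q_threshold Maximum BH q-value admitted (default 0.05).
#' @param min_abs_ls Minimum absolute LS score admitted (default 0).
#' @param categories Optional named character vector mapping variable names
#'   to categories (e.g. `"kinetic_param"`, `"primary_producer"`,
#'   `"bacterial_group"`), carried as node metadata for Cytoscape styling.
#' @return Object of class `association_network`: list with `nodes`
#'   (tibble: `name`, `category`, `enzyme`, `system`) and `edges` (tibble:
#'   `var_x`, `var_y`, `sign`, `delay`, `ls_score`, `q_value`, `directed`).
#' @export
build_network <- function(results, q_threshold = 0.05, min_abs_ls = 0,
                          categories = NULL) {
  results <- as.data.frame(results)
  if (nrow(results) == 0L) stop("empty results", call. = FALSE)
  if (!"q_value" %in% names(results)) stop("results carry no q-values", call. = FALSE)
  if (any(results$var_x == results$var_y)) stop("self-pairs are not allowed", call. = FALSE)

  nms <- sort(unique(c(results$var_x, results$var_y)))
  tags <- lapply(nms, parse_node_tags)
  nodes <- tibble::tibble(
    name = nms,
    category = if (is.null(categories)) NA_character_ else
      unname(categories[nms]),
    enzyme = vapply(tags, `[[`, character(1L), "enzyme"),
    system = vapply(tags, `[[`, character(1L), "system")
  )
  keep <- results$q_value <= q_threshold & abs(results$ls_score) >= min_abs_ls
  ed <- results[keep, , drop = FALSE]
  edges <- tibble::tibble(
    var_x = ed$var_x, var_y = ed$var_y,
    sign = ifelse(ed$ls_score >= 0, 1L, -1L),
    delay = as.integer(ed$delay),
    ls_score = ed$ls_score, q_value = ed$q_value,
    directed = ed$delay != 0L
  )
  structure(list(nodes = nodes, edges = edges), class = "association_network")
}

#' @export
print.association_network <- function(x, ...) {
  cat(sprintf("<association_network> %d nodes, %d edges (%d delayed)\n",
              nrow(x$nodes), nrow(x$edges), sum(x$edges$directed)))
  invisible(x)
}

## canonical orientation: delayed edges run leader -> follower
oriented_edges <- function(net) {
  e <- net$edges
  flip <- e$delay < 0L
  out <- e
  out$var_x[flip] <- e$var_y[flip]
  out$var_y[flip] <- e$var_x[flip]
  out$delay <- abs(e$delay)
  out
}

#' Export an association network for Cytoscape
#'
#' Three interchange formats are supported:
#' * `"sif"` — simple interaction format, one edge per line with interaction
#'   labels `pos_d0`, `pos_d1`, `neg_d0`, `neg_d1` (sign and delay
#'   magnitude); isolated nodes are emitted as bare node lines.
#' * `"graphml"` — full node and edge attributes via igraph; round-trips
#'   through [import_network()].
#' * `"csv"` — edge table with all attributes.
#'
#' Delayed edges are written leader first.
#'
#' @param net An [build_network()] result.
#' @param path Output file path.
#' @param format `"sif"`, `"graphml"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("sif", "graphml", "csv")) {
  stopifnot(inherits(net, "association_network"))
  format <- match.arg(format)
  e <- oriented_edges(net)
  if (format == "sif") {
    lines <- character(0)
    if (nrow(e) > 0L) {
      lab <- sprintf("%s_d%d", ifelse(e$sign > 0, "pos", "neg"), e$delay)
      lines <- paste(e$var_x, lab, e$var_y, sep = "\t")
    }
    isolated <- setdiff(net$nodes$name, c(e$var_x, e$var_y))
    writeLines(c(lines, isolated), path)
  } else if (format == "csv") {
    write.csv(as.data.frame(e), path, row.names = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      as.data.frame(e), directed = TRUE,
      vertices = as.data.frame(net$nodes))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Import a GraphML association network
#'
#' Inverse of [export_network()] with `format = "graphml"`: restores the
#' node and edge tables written by the export.
#'
#' @param path GraphML file path.
#' @return An `association_network`.
#' @export
import_network <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  vd <- igraph::as_data_frame(g, what = "vertices")
  ed <- igraph::as_data_frame(g, what = "edges")
  nodes <- tibble::tibble(
    name = vd$name,
    category = if ("category" %in% names(vd)) vd$category else NA_character_,
    enzyme = if ("enzyme" %in% names(vd)) vd$enzyme else NA_character_,
    system = if ("system" %in% names(vd)) vd$system else NA_character_
  )
  nodes <- nodes[order(nodes$name), ]
  if (nrow(ed) > 0L) {
    edges <- tibble::tibble(
      var_x = ed$from, var_y = ed$to,
      sign = as.integer(ed$sign), delay = as.integer(ed$delay),
      ls_score = as.numeric(ed$ls_score), q_value = as.numeric(ed$q_value),
      directed = as.logical(ed$directed)
    )
  } else {
    edges <- tibble::tibble(var_x = character(0), var_y = character(0),
                            sign = integer(0), delay = integer(0),
                            ls_score = numeric(0), q_value = numeric(0),
                            directed = logical(0))
  }
  structure(list(nodes = nodes, edges = edges), class = "association_network")
}
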