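#' Write a transport network to GraphML or nodes/edges CSV
#'
#' Edges are serialized in their undirected representation (one row per
#' two-way edge, `oneway` flag on directed ones); [read_network()] re-expands
#' reciprocal directed edges. CSV output writes `<base>_nodes.csv` and
#' `<base>_edges.csv`.
#'
#' @param network a `transport_network`.
#' @param path output path (`.graphml` selects GraphML, anything else CSV).
#' @param format "graphml" or "csv"; inferred from `path` when missing.
#' @return invisibly the path(s) written.
#' @export
write_network <- function(network, path,
                          format = if (grepl("\\.graphml$", path)) "graphml" else "csv") {
  e <- undirected_edge_view(network)
  if (format == "graphml") {
    doc <- xml2::xml_new_root("graphml",
                              xmlns = "http://graphml.graphdrawing.org/xmlns")
    keydefs <- list(c("kx", "node", "x", "double"),
                    c("ky", "node", "y", "double"),
                    c("kl", "edge", "length_km", "double"),
                    c("ks", "edge", "speed_kmh", "double"),
                    c("km", "edge", "mode", "string"),
                    c("ko", "edge", "oneway", "boolean"))
    for (k in keydefs)
      xml2::xml_add_child(doc, "key", id = k[1L], "for" = k[2L],
                          "attr.name" = k[3L], "attr.type" = k[4L])
    g <- xml2::xml_add_child(doc, "graph", edgedefault = "directed")
    for (i in seq_len(nrow(network$nodes))) {
      nd <- xml2::xml_add_child(g, "node", id = network$nodes$id[i])
      xml2::xml_add_child(nd, "data", key = "kx",
                          sprintf("%.10g", network$nodes$x[i]))
      xml2::xml_add_child(nd, "data", key = "ky",
                          sprintf("%.10g", network$nodes$y[i]))
    }
    for (i in seq_len(nrow(e))) {
      ed <- xml2::xml_add_child(g, "edge", source = e$u[i], target = e$v[i])
      xml2::xml_add_child(ed, "data", key = "kl", sprintf("%.10g", e$length_km[i]))
      xml2::xml_add_child(ed, "data", key = "ks", sprintf("%.10g", e$speed_kmh[i]))
      xml2::xml_add_child(ed, "data", key = "km", e$mode[i])
      xml2::xml_add_child(ed, "data", key = "ko", tolower(as.character(e$oneway[i])))
    }
    xml2::write_xml(doc, path)
    return(invisible(path))
  }
  base <- sub("\\.csv$", "", path)
  np <- paste0(base, "_nodes.csv"); ep <- paste0(base, "_edges.csv")
  utils::write.csv(network$nodes, np, row.names = FALSE, quote = FALSE)
  utils::write.csv(e[, c("u", "v", "length_km", "speed_kmh", "mode", "oneway")],
                   ep, row.names = FALSE, quote = FALSE)
  invisible(c(np, ep))
}

#' Read a transport network from GraphML or nodes/edges CSV
#'
#' Two-way edges are expanded to reciprocal directed edges. Missing speeds
#' are filled from [class_default_speeds()] with a warning. Edges that
#' reference unknown nodes or carry non-positive lengths raise format errors.
#'
#' @param path a `.graphml` file, or a length-2 vector
#'   `c(nodes.csv, edges.csv)`, or the base path of a CSV pair.
#' @return a `transport_network`.
#' @export
read_network <- function(path) {
  if (length(path) == 1L && grepl("\\.graphml$", path)) {
    doc <- xml2::read_xml(path)
    ns <- xml2::xml_ns_rename(xml2::xml_ns(doc), d1 = "g")
    keys <- xml2::xml_find_all(doc, ".//g:key", ns)
    keymap <- stats::setNames(xml2::xml_attr(keys, "attr.name"),
                              xml2::xml_attr(keys, "id"))
    nodes_xml <- xml2::xml_find_all(doc, ".//g:node", ns)
    get_data <- function(el) {
      d <- xml2::xml_find_all(el, "./g:data", ns)
      stats::setNames(xml2::xml_text(d),
                      unname(keymap[xml2::xml_attr(d, "key")]))
    }
    nodes <- do.call(rbind.data.frame, lapply(nodes_xml, function(nd) {
      a <- get_data(nd)
      list(id = xml2::xml_attr(nd, "id"),
           x = as.numeric(a[["x"]]), y = as.numeric(a[["y"]]))
    }))
    edges_xml <- xml2::xml_find_all(doc, ".//g:edge", ns)
    edges <- do.call(rbind.data.frame, lapply(edges_xml, function(ed) {
      a <- get_data(ed)
      list(u = xml2::xml_attr(ed, "source"),
           v = xml2::xml_attr(ed, "target"),
           length_km = as.numeric(a[["length_km"]]),
           speed_kmh = if ("speed_kmh" %in% names(a))
             as.numeric(a[["speed_kmh"]]) else NA_real_,
           mode = if ("mode" %in% names(a)) a[["mode"]] else "primary",
           oneway = if ("oneway" %in% names(a))
             identical(a[["oneway"]], "true") else FALSE)
    }))
    return(transport_network(nodes, edges))
  }
  if (length(path) == 1L) path <- paste0(sub("\\.csv$", "", path),
                                         c("_nodes.csv", "_edges.csv"))
  nodes <- utils::read.csv(path[1L], stringsAsFactors = FALSE)
  edges <- utils::read.csv(path[2L], stringsAsFactors = FALSE)
  if (nrow(edges)) {
    if (is.character(edges$oneway))
      edges$oneway <- tolower(edges$oneway) %in% c("true", "t", "1", "yes")
    bad <- !is.na(edges$length_km) & edges$length_km <= 0
    if (any(bad))
      stop(sprintf("edges.csv row %d: non-positive length", which(bad)[1L]))
  }
  transport_network(nodes, edges)
}
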