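#' Read pathway graphs from the tabular edge-list format
#'
#' The canonical pathway exchange format is UTF-8 tab-separated text with a
#' header line and one row per directed edge. Required columns:
#' `pathway_id`, `edge_id`, `reactants` (semicolon-joined protein ids),
#' `products` (semicolon-joined), and `interaction`, which must be
#' `"activation"` (mapped to catalysis) or `"inhibition"`. Lines starting
#' with `#` are comments. Nodes are identified by their sorted member set,
#' so rows listing the same protein set share a node.
#'
#' @param file Path to a file, or a connection.
#' @return Named list of [pathway_graph] objects, one per distinct
#'   `pathway_id`, in order of first appearance.
#' @export
parse_pathway_table <- function(file) {
  tab <- utils::read.delim(file, comment.char = "#", stringsAsFactors = FALSE,
                           colClasses = "character", blank.lines.skip = TRUE)
  required <- c("pathway_id", "edge_id", "reactants", "products", "interaction")
  missing_cols <- setdiff(required, names(tab))
  if (length(missing_cols))
    stop("pathway table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  if (!nrow(tab)) return(list())
  # line numbers in the source file: header is line 1 (comments shift these,
  # but read.delim drops them silently; report data-row index instead)
  for (i in seq_len(nrow(tab))) {
    inter <- tab$interaction[i]
    if (!inter %in% c("activation", "inhibition"))
      stop("pathway table row ", i, ": unknown interaction keyword '", inter, "'")
    if (!nzchar(gsub(";", "", tab$reactants[i])) ||
        !nzchar(gsub(";", "", tab$products[i])))
      stop("pathway table row ", i, ": empty reactant or product member list")
  }
  split_members <- function(s) {
    mem <- strsplit(s, ";", fixed = TRUE)[[1L]]
    mem <- mem[nzchar(mem)]
    mem
  }
  graphs <- list()
  for (pid in unique(tab$pathway_id)) {
    rows <- tab[tab$pathway_id == pid, , drop = FALSE]
    nodes <- list()
    reactant_ids <- character(nrow(rows))
    product_ids <- character(nrow(rows))
    for (i in seq_len(nrow(rows))) {
      rmem <- split_members(rows$reactants[i])
      pmem <- split_members(rows$products[i])
      rid <- node_id_for(rmem)
      pid2 <- node_id_for(pmem)
      nodes[[rid]] <- sort(unique(rmem))
      nodes[[pid2]] <- sort(unique(pmem))
      reactant_ids[i] <- rid
      product_ids[i] <- pid2
    }
    edges <- data.frame(
      edge_id = rows$edge_id,
      reactant = reactant_ids,
      product = product_ids,
      kind = ifelse(rows$interaction == "activation", "catalysis", "inhibition"),
      stringsAsFactors = FALSE
    )
    graphs[[pid]] <- pathway_graph(pid, nodes, edges)
  }
  graphs
}

#' Write pathway graphs in the tabular edge-list format
#'
#' Inverse of [parse_pathway_table()]: emits one row per edge with
#' semicolon-joined member sets. Parsing the output reproduces the graphs
#' field-for-field (after canonicalization of node ids and edge order).
#'
#' @param graphs A `pathway_graph` or list of them.
#' @param file Path or connection to write to.
#' @return `file`, invisibly.
#' @export
write_pathway_table <- function(graphs, file) {
  if (inherits(graphs, "pathway_graph")) graphs <- list(graphs)
  rows <- lapply(graphs, function(g) {
    e <- g$edges
    if (!nrow(e)) return(NULL)
    data.frame(
      pathway_id = g$pathway_id,
      edge_id = e$edge_id,
      reactants = vapply(e$reactant, function(id) paste(g$nodes[[id]], collapse = ";"), ""),
      products = vapply(e$product, function(id) paste(g$nodes[[id]], collapse = ";"), ""),
      interaction = ifelse(e$kind == "catalysis", "activation", "inhibition"),
      stringsAsFactors = FALSE
    )
  })
  tab <- do.call(rbind, rows)
  utils::write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read gene sets from a GMT file
#'
#' GMT is the standard gene-set exchange format: one set per line,
#' tab-separated as `name`, `description`, then member identifiers. Used by
#' the set-based statistic variant, which ignores pathway topology.
#'
#' @param file Path to a GMT file.
#' @return Named list of character vectors of member identifiers.
#' @export
read_gmt <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stop("GMT line with fewer than 3 fields: ", substr(ln, 1, 60))
    sets[[parts[1L]]] <- unique(parts[-(1:2)][nzchar(parts[-(1:2)])])
  }
  sets
}

#' Minimal SBML pathway import
#'
#' Best-effort importer for SBML Level 2/3 documents in the style of the
#' PANTHER pathway exports: each reaction with at least one reactant and one
#' product species becomes a catalytic edge from the reactant set to the
#' product set, and each modifier species becomes an additional edge from
#' the modifier to the product set. Modifiers annotated as inhibitors
#' (SBO:0000020 or SBO:0000537 on the modifier reference) yield inhibitory
#' edges; all other modifiers are treated as catalysts. Reactions without a
#' usable reactant/product pair are skipped with a warning; the import is
#' lossy but never silently so.
#'
#' @param file Path to an SBML file.
#' @return Named list of [pathway_graph] objects (one per `<model>`).
#' @export
import_sbml_minimal <- function(file) {
  doc <- xml2::read_xml(file)
  models <- xml2::xml_find_all(doc, ".//*[local-name() = 'model']")
  if (!length(models)) {
    warning("SBML document contains no <model>; returning an empty collection")
    return(list())
  }
  inhibitor_sbo <- c("SBO:0000020", "SBO:0000537")
  graphs <- list()
  for (model in models) {
    model_id <- xml2::xml_attr(model, "id")
    if (is.na(model_id) || !nzchar(model_id)) model_id <- "sbml_model"
    # species id -> display name (fall back to the id)
    sp_nodes <- xml2::xml_find_all(model, ".//*[local-name() = 'species']")
    sp_id <- xml2::xml_attr(sp_nodes, "id")
    sp_name <- xml2::xml_attr(sp_nodes, "name")
    sp_name[is.na(sp_name) | !nzchar(sp_name)] <- sp_id[is.na(sp_name) | !nzchar(sp_name)]
    species <- stats::setNames(sp_name, sp_id)
    reactions <- xml2::xml_find_all(model, ".//*[local-name() = 'reaction']")
    nodes <- list()
    edge_rows <- list()
    skipped <- 0L
    refs <- function(rx, listname) {
      nd <- xml2::xml_find_all(
        rx, sprintf(".//*[local-name() = '%s']/*[local-name() = 'speciesReference' or local-name() = 'modifierSpeciesReference']",
                    listname))
      nd
    }
    members_of <- function(ref_nodes) {
      ids <- xml2::xml_attr(ref_nodes, "species")
      mem <- unname(species[ids])
      mem[is.na(mem)] <- ids[is.na(mem)]
      mem[!is.na(mem) & nzchar(mem)]
    }
    for (k in seq_along(reactions)) {
      rx <- reactions[[k]]
      rx_id <- xml2::xml_attr(rx, "id")
      if (is.na(rx_id) || !nzchar(rx_id)) rx_id <- sprintf("reaction%03d", k)
      rmem <- members_of(refs(rx, "listOfReactants"))
      pmem <- members_of(refs(rx, "listOfProducts"))
      mod_refs <- refs(rx, "listOfModifiers")
      if (!length(pmem) || (!length(rmem) && !length(mod_refs))) {
        skipped <- skipped + 1L
        next
      }
      pid <- node_id_for(pmem)
      nodes[[pid]] <- sort(unique(pmem))
      if (length(rmem)) {
        rid <- node_id_for(rmem)
        nodes[[rid]] <- sort(unique(rmem))
        edge_rows[[length(edge_rows) + 1L]] <- data.frame(
          edge_id = rx_id, reactant = rid, product = pid,
          kind = "catalysis", stringsAsFactors = FALSE)
      }
      for (j in seq_along(mod_refs)) {
        mmem <- members_of(mod_refs[j])
        if (!length(mmem)) next
        mid <- node_id_for(mmem)
        nodes[[mid]] <- sort(unique(mmem))
        sbo <- xml2::xml_attr(mod_refs[[j]], "sboTerm")
        kind <- if (!is.na(sbo) && sbo %in% inhibitor_sbo) "inhibition" else "catalysis"
        edge_rows[[length(edge_rows) + 1L]] <- data.frame(
          edge_id = sprintf("%s_mod%d", rx_id, j), reactant = mid, product = pid,
          kind = kind, stringsAsFactors = FALSE)
      }
    }
    if (skipped > 0L)
      warning(sprintf("SBML model '%s': skipped %d reaction(s) without mappable species",
                      model_id, skipped))
    if (!length(edge_rows)) {
      warning(sprintf("SBML model '%s': no usable reactions; model skipped", model_id))
      next
    }
    graphs[[model_id]] <- pathway_graph(model_id, nodes, do.call(rbind, edge_rows))
  }
  graphs
}
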