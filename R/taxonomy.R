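# Taxonomy trees and rank-penalized distances.
#
# Distances are computed on the unique up-to-LCA-and-down path of a rooted
# tree. Each traversed node (every node on the path except the start node,
# including the LCA and the end node) contributes the penalty of its rank;
# crossing between domains adds a single flat surcharge. The taxonomic
# similarity downstream is 1 - distance / maxdistance, so the penalized tree
# diameter serves as the normalizer.

#' Controlled vocabulary of taxonomic ranks
#'
#' Ranks recognized by the taxonomy module, from broadest to narrowest, plus
#' `no_rank` for unranked nodes. Unknown rank strings encountered while
#' loading a tree are coerced to `no_rank` with a warning.
#'
#' @format Character vector of length 10.
#' @export
taxonomy_ranks <- c(
  "domain", "kingdom", "phylum", "class", "order",
  "family", "genus", "species", "strain", "no_rank"
)

#' Penalty schedule for rank-penalized taxonomy distances
#'
#' Traversing a node on the path between two organisms costs the penalty of
#' that node's rank; paths that cross between domains incur
#' `domain_crossing_penalty` once on top. `missing_lineage_decrement` is the
#' amount subtracted from the taxonomic similarity score per lineage-fallback
#' step when an organism is absent from the tree.
#'
#' The default schedule increases cost with rank height (species-level nodes
#' are cheap to traverse, kingdom-level nodes expensive) and the
#' domain-crossing surcharge dominates every per-rank cost, so inter-domain
#' pairs always score as most distant.
#'
#' @param per_rank_penalty Named numeric vector, one strictly positive cost
#'   per rank in [taxonomy_ranks].
#' @param domain_crossing_penalty Single positive cost added when the path
#'   crosses between domains; must be at least `max(per_rank_penalty)`.
#' @param missing_lineage_decrement Non-negative similarity decrement per
#'   lineage-fallback step.
#' @return An object of class `penalty_schedule`.
#' @export
penalty_schedule <- function(per_rank_penalty = c(
                               domain = 8, kingdom = 8, phylum = 6,
                               class = 5, order = 4, family = 3, genus = 2,
                               species = 1, strain = 1, no_rank = 1
                             ),
                             domain_crossing_penalty = 16,
                             missing_lineage_decrement = 0.05) {
  missing <- setdiff(taxonomy_ranks, names(per_rank_penalty))
  if (length(missing)) {
    rr_error(paste0("per_rank_penalty lacks ranks: ",
                    paste(missing, collapse = ", ")),
             "rescuerank_config_error")
  }
  if (any(!is.finite(per_rank_penalty)) || any(per_rank_penalty <= 0)) {
    rr_error("all per-rank penalties must be strictly positive",
             "rescuerank_config_error")
  }
  if (!is.finite(domain_crossing_penalty) || domain_crossing_penalty <= 0 ||
      domain_crossing_penalty < max(per_rank_penalty)) {
    rr_error(
      "domain_crossing_penalty must be positive and >= max(per_rank_penalty)",
      "rescuerank_config_error"
    )
  }
  if (missing_lineage_decrement < 0) {
    rr_error("missing_lineage_decrement must be >= 0",
             "rescuerank_config_error")
  }
  structure(
    list(
      per_rank_penalty = per_rank_penalty[taxonomy_ranks],
      domain_crossing_penalty = domain_crossing_penalty,
      missing_lineage_decrement = missing_lineage_decrement
    ),
    class = "penalty_schedule"
  )
}

#' Read a penalty schedule from a flat key = value config file
#'
#' Keys are rank names plus `domain_crossing_penalty` and
#' `missing_lineage_decrement`; unspecified keys keep their defaults.
#'
#' @param path Path to the config file.
#' @return A [penalty_schedule()].
#' @export
read_penalty_schedule <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2L
  if (any(bad)) {
    rr_error(paste0("unparseable schedule line: ", lines[bad][1L]),
             "rescuerank_config_error")
  }
  keys <- vapply(kv, `[`, "", 1L)
  vals <- suppressWarnings(as.numeric(vapply(kv, `[`, "", 2L)))
  if (anyNA(vals)) {
    rr_error("non-numeric value in penalty schedule file",
             "rescuerank_config_error")
  }
  default <- penalty_schedule()
  per <- default$per_rank_penalty
  rank_keys <- intersect(keys, taxonomy_ranks)
  per[rank_keys] <- vals[match(rank_keys, keys)]
  penalty_schedule(
    per_rank_penalty = per,
    domain_crossing_penalty =
      if ("domain_crossing_penalty" %in% keys)
        vals[match("domain_crossing_penalty", keys)]
      else default$domain_crossing_penalty,
    missing_lineage_decrement =
      if ("missing_lineage_decrement" %in% keys)
        vals[match("missing_lineage_decrement", keys)]
      else default$missing_lineage_decrement
  )
}

#' Build a validated taxonomy tree from node records
#'
#' @param nodes A data.frame with columns `taxon_id`, `parent_id`, `rank`
#'   and optionally `name`. The root is the single row whose `parent_id` is
#'   `NA` or equal to its own `taxon_id`.
#' @return An object of class `taxonomy_tree` with elements `nodes`
#'   (data.frame) and `root_id`.
#' @details Unknown rank strings are coerced to `no_rank` with a warning.
#'   Duplicate ids, dangling parents and cyclic parent chains are structural
#'   errors naming the offending taxon id.
#' @export
taxonomy_tree <- function(nodes) {
  req <- c("taxon_id", "parent_id", "rank")
  if (!all(req %in% names(nodes))) {
    rr_error("nodes must have columns taxon_id, parent_id, rank",
             "rescuerank_structure_error")
  }
  nodes <- as.data.frame(nodes, stringsAsFactors = FALSE)
  nodes$taxon_id <- as.integer(nodes$taxon_id)
  nodes$parent_id <- suppressWarnings(as.integer(nodes$parent_id))
  nodes$rank <- as.character(nodes$rank)
  if (!"name" %in% names(nodes)) nodes$name <- as.character(nodes$taxon_id)
  if (nrow(nodes) == 0L) {
    rr_error("empty taxonomy", "rescuerank_structure_error")
  }
  if (anyDuplicated(nodes$taxon_id)) {
    dup <- nodes$taxon_id[duplicated(nodes$taxon_id)][1L]
    rr_error(paste0("duplicate taxon_id: ", dup), "rescuerank_structure_error")
  }
  unknown <- !(nodes$rank %in% taxonomy_ranks)
  if (any(unknown)) {
    rr_warn(paste0("unknown rank(s) coerced to no_rank: ",
                   paste(unique(nodes$rank[unknown]), collapse = ", ")))
    nodes$rank[unknown] <- "no_rank"
  }
  # self-parenting row (NCBI taxdump convention) marks the root
  nodes$parent_id[!is.na(nodes$parent_id) &
                    nodes$parent_id == nodes$taxon_id] <- NA_integer_
  roots <- nodes$taxon_id[is.na(nodes$parent_id)]
  if (length(roots) != 1L) {
    rr_error(paste0("tree must have exactly one root, found ", length(roots)),
             "rescuerank_structure_error")
  }
  dangling <- !is.na(nodes$parent_id) &
    !(nodes$parent_id %in% nodes$taxon_id)
  if (any(dangling)) {
    rr_error(paste0("dangling parent_id ", nodes$parent_id[dangling][1L],
                    " for taxon ", nodes$taxon_id[dangling][1L]),
             "rescuerank_structure_error")
  }
  # cycle check by peeling from the root: nodes never reached sit on a cycle
  parent_idx <- match(nodes$parent_id, nodes$taxon_id)
  depth <- rep(NA_integer_, nrow(nodes))
  depth[is.na(parent_idx)] <- 0L
  repeat {
    reach <- is.na(depth) & !is.na(depth[parent_idx])
    if (!any(reach)) break
    depth[reach] <- depth[parent_idx[reach]] + 1L
  }
  if (anyNA(depth)) {
    rr_error(paste0("cyclic parent chain involving taxon ",
                    nodes$taxon_id[is.na(depth)][1L]),
             "rescuerank_structure_error")
  }
  structure(
    list(nodes = nodes, root_id = roots, depth = depth,
         parent_idx = parent_idx),
    class = "taxonomy_tree"
  )
}

#' Load a taxonomy tree from a flat file
#'
#' Accepts either a simplified 4-column TSV (`taxon_id`, `parent_id`,
#' `rank`, `name`, with a header) or an NCBI-taxdump-style nodes table
#' (fields separated by `\t|\t`, rows terminated by `\t|`), optionally
#' paired with a taxdump names table for scientific names.
#'
#' @param nodes_path Path to the nodes file.
#' @param names_path Optional path to a taxdump-dialect names file.
#' @param format `"auto"` (default), `"tsv"` or `"taxdump"`.
#' @return A `taxonomy_tree`.
#' @export
load_taxonomy <- function(nodes_path, names_path = NULL, format = "auto") {
  if (!file.exists(nodes_path)) {
    rr_error(paste0("taxonomy file not found: ", nodes_path),
             "rescuerank_config_error")
  }
  lines <- readLines(nodes_path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "auto") {
    format <- if (length(lines) && grepl("\t\\|", lines[1L])) "taxdump"
    else "tsv"
  }
  if (format == "taxdump") {
    fields <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
    nodes <- data.frame(
      taxon_id = as.integer(vapply(fields, `[`, "", 1L)),
      parent_id = as.integer(vapply(fields, `[`, "", 2L)),
      rank = gsub("\\s+", "_", trimws(vapply(fields, `[`, "", 3L))),
      stringsAsFactors = FALSE
    )
    # NCBI spells unranked nodes "no rank" and has no domain rank;
    # superkingdom plays that role
    nodes$rank[nodes$rank == "superkingdom"] <- "domain"
    if (!is.null(names_path) && file.exists(names_path)) {
      nl <- readLines(names_path, warn = FALSE)
      nf <- strsplit(sub("\t\\|$", "", nl[nzchar(nl)]), "\t\\|\t")
      cls <- vapply(nf, function(f) trimws(f[4L] %||% ""), "")
      keep <- cls %in% c("scientific name", "")
      nm <- data.frame(
        taxon_id = as.integer(vapply(nf[keep], `[`, "", 1L)),
        name = trimws(vapply(nf[keep], `[`, "", 2L)),
        stringsAsFactors = FALSE
      )
      nodes$name <- nm$name[match(nodes$taxon_id, nm$taxon_id)]
      nodes$name[is.na(nodes$name)] <- as.character(
        nodes$taxon_id[is.na(nodes$name)]
      )
    }
  } else {
    nodes <- utils::read.delim(nodes_path, stringsAsFactors = FALSE)
    if (!all(c("taxon_id", "parent_id", "rank") %in% names(nodes))) {
      rr_error("TSV taxonomy needs header taxon_id, parent_id, rank[, name]",
               "rescuerank_structure_error")
    }
  }
  taxonomy_tree(nodes)
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("Taxonomy tree:", nrow(x$nodes), "nodes, root", x$root_id,
      paste0("(", sum(!(x$nodes$taxon_id %in% x$nodes$parent_id)), " leaves)"),
      "\n")
  invisible(x)
}

tax_index <- function(tree, id) {
  i <- match(as.integer(id), tree$nodes$taxon_id)
  if (is.na(i)) {
    rr_error(paste0("taxon ", id, " not in tree"),
             "rescuerank_unresolvable_taxon")
  }
  i
}

# Ancestor chain of indices from a node (inclusive) up to the root.
ancestor_chain <- function(tree, idx) {
  chain <- integer(tree$depth[idx] + 1L)
  k <- 0L
  while (!is.na(idx)) {
    k <- k + 1L
    chain[k] <- idx
    idx <- tree$parent_idx[idx]
  }
  chain
}

# Nearest ancestor (inclusive) of rank "domain", or NA.
domain_of <- function(tree, idx) {
  chain <- ancestor_chain(tree, idx)
  dom <- chain[tree$nodes$rank[chain] == "domain"]
  if (length(dom)) tree$nodes$taxon_id[dom[1L]] else NA_integer_
}

#' Resolve a taxon against a tree with lineage fallback
#'
#' When an organism is absent from the tree its lineage (immediate parent
#' first) is walked upwards until a known ancestor is found; the number of
#' hops consumed is reported so the caller can decrement the similarity
#' score accordingly.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxon_id Taxon to resolve.
#' @param lineage Integer vector of ancestor ids, ordered from immediate
#'   parent to root; may be empty.
#' @return A list with `node` (one-row data.frame) and `fallback_steps`.
#' @export
resolve_with_fallback <- function(tree, taxon_id, lineage = integer(0)) {
  candidates <- c(as.integer(taxon_id), as.integer(lineage))
  hit <- match(candidates, tree$nodes$taxon_id)
  found <- which(!is.na(hit))
  if (!length(found)) {
    rr_error(paste0("taxon ", taxon_id,
                    " unresolvable: neither it nor its lineage is in the tree"),
             "rescuerank_unresolvable_taxon")
  }
  k <- found[1L]
  list(node = tree$nodes[hit[k], ], fallback_steps = k - 1L)
}

#' Rank-penalized distance between two taxa
#'
#' Sums the per-rank penalty of every node on the unique tree path from `a`
#' to `b` except the lowest common ancestor (equivalently, each edge on the
#' path charges the penalty of its deeper endpoint), and adds the
#' domain-crossing surcharge once when the two taxa fall under different
#' domain-rank ancestors. This makes the distance symmetric, zero exactly
#' for identical taxa, and one rank penalty for a parent-child pair.
#'
#' @param tree A `taxonomy_tree`.
#' @param a,b Taxon ids present in the tree.
#' @param schedule A [penalty_schedule()].
#' @return An object of class `taxonomic_distance`: `raw_distance`, `path`
#'   (taxon ids from `a` to `b`), `crossed_domain`, `fallback_steps` (always
#'   0 here; set by callers that resolved via lineage fallback).
#' @export
penalized_distance <- function(tree, a, b, schedule = penalty_schedule()) {
  ia <- tax_index(tree, a)
  ib <- tax_index(tree, b)
  if (ia == ib) {
    return(structure(
      list(raw_distance = 0, path = tree$nodes$taxon_id[ia],
           crossed_domain = FALSE, fallback_steps = 0L),
      class = "taxonomic_distance"
    ))
  }
  ca <- ancestor_chain(tree, ia)
  cb <- ancestor_chain(tree, ib)
  common <- intersect(ca, cb)
  lca <- common[1L]  # chains are ordered leaf-to-root; first shared = LCA
  up <- ca[seq_len(match(lca, ca))]          # a .. lca inclusive
  down <- rev(cb[seq_len(match(lca, cb) - 1L)])  # below-lca .. b
  path_idx <- c(up, down)
  traversed <- path_idx[path_idx != lca]
  raw <- sum(schedule$per_rank_penalty[tree$nodes$rank[traversed]])
  da <- domain_of(tree, ia)
  db <- domain_of(tree, ib)
  crossed <- !is.na(da) && !is.na(db) && da != db
  if (crossed) raw <- raw + schedule$domain_crossing_penalty
  structure(
    list(raw_distance = unname(raw),
         path = tree$nodes$taxon_id[path_idx],
         crossed_domain = crossed, fallback_steps = 0L),
    class = "taxonomic_distance"
  )
}

#' @export
print.taxonomic_distance <- function(x, ...) {
  cat("Penalized taxonomic distance:", x$raw_distance,
      if (x$crossed_domain) "(crossed domains)" else "", "\n")
  cat("  path:", paste(x$path, collapse = " -> "), "\n")
  invisible(x)
}

tree_leaves <- function(tree) {
  tree$nodes$taxon_id[!(tree$nodes$taxon_id %in% tree$nodes$parent_id)]
}

# Penalized distance from the root to every node, used by the diameter
# heuristic on large trees.
root_distances <- function(tree, schedule) {
  parent_idx <- match(tree$nodes$parent_id, tree$nodes$taxon_id)
  pen <- schedule$per_rank_penalty[tree$nodes$rank]
  d <- rep(NA_real_, nrow(tree$nodes))
  ord <- order(tree$depth)
  for (i in ord) {
    d[i] <- if (is.na(parent_idx[i])) 0 else d[parent_idx[i]] + pen[i]
  }
  d
}

#' Penalized diameter of a taxonomy tree
#'
#' The normalizer for the taxonomic similarity score: the maximum penalized
#' distance over leaf pairs. Computed exactly by enumerating all leaf pairs
#' for trees up to `exact_limit` nodes; larger trees use the deepest leaves
#' per domain (by penalized depth) as diameter candidates. A single-node
#' tree returns `floor` so division is always defined.
#'
#' @param tree A `taxonomy_tree`.
#' @param schedule A [penalty_schedule()].
#' @param exact_limit Node count up to which all leaf pairs are enumerated.
#' @param floor Value returned for a single-node tree (default 1.0).
#' @return A positive scalar, at least as large as any `penalized_distance`
#'   on the same tree.
#' @export
max_distance <- function(tree, schedule = penalty_schedule(),
                         exact_limit = 500L, floor = 1.0) {
  leaves <- tree_leaves(tree)
  if (nrow(tree$nodes) == 1L || length(leaves) < 2L) return(floor)
  if (nrow(tree$nodes) <= exact_limit) {
    cand <- leaves
  } else {
    rd <- root_distances(tree, schedule)
    leaf_idx <- match(leaves, tree$nodes$taxon_id)
    dom <- vapply(leaf_idx, function(i) domain_of(tree, i), integer(1))
    cand <- unlist(lapply(split(leaf_idx, dom, drop = TRUE), function(ix) {
      ix[order(rd[ix], decreasing = TRUE)][seq_len(min(2L, length(ix)))]
    }))
    cand <- tree$nodes$taxon_id[cand]
  }
  best <- 0
  for (i in seq_along(cand)) {
    for (j in seq_len(i - 1L)) {
      d <- penalized_distance(tree, cand[i], cand[j], schedule)$raw_distance
      if (d > best) best <- d
    }
  }
  max(best, floor)
}
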