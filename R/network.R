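#' Upper-tail hypergeometric overlap test
#'
#' `P(X >= k)` for `X ~ Hypergeometric(universe_size, |A|, |B|)` with
#' `k = |A intersect B|`. The universe is the full gene background (e.g. all
#' protein-coding genes).
#'
#' @param set_a,set_b Character vectors of gene ids (subsets of the
#'   universe), or integers `|A|`/`|B|` if `overlap` is given.
#' @param universe_size Size of the background universe.
#' @param overlap Optional explicit overlap count `k` (required when sets are
#'   given as sizes).
#' @return The upper-tail p-value.
#' @export
hypergeometric_overlap <- function(set_a, set_b, universe_size,
                                   overlap = NULL) {
  if (is.null(overlap)) {
    k <- length(intersect(set_a, set_b))
    na <- length(unique(set_a))
    nb <- length(unique(set_b))
  } else {
    k <- overlap
    na <- set_a
    nb <- set_b
  }
  if (na > universe_size || nb > universe_size) {
    abort("set sizes exceed universe")
  }
  if (k > min(na, nb)) abort("overlap exceeds the smaller set")
  stats::phyper(k - 1, na, universe_size - na, nb, lower.tail = FALSE)
}

#' Term enrichment over an annotation map
#'
#' Hypergeometric enrichment of a gene set against each term of a local
#' annotation map (term -> gene set), BH-adjusted across terms and sorted by
#' FDR. Significant terms have FDR < 0.05.
#'
#' @param geneset Character vector of gene ids.
#' @param term_map Named list (term -> character vector of gene ids) or a
#'   two-column tibble (`term`, `gene_id`).
#' @param universe Character vector of background genes (or its size).
#' @param fdr Significance threshold (default 0.05).
#' @return Tibble `term`, `n_term`, `overlap`, `p`, `fdr`, `significant`,
#'   `genes` (list-column).
#' @export
term_enrichment <- function(geneset, term_map, universe, fdr = 0.05) {
  n_univ <- if (is.numeric(universe)) universe else length(universe)
  if (is.data.frame(term_map)) {
    term_map <- split(term_map$gene_id, term_map$term)
  }
  if (length(geneset) == 0) {
    message("empty gene set; no enrichment computed")
    return(tibble(term = character(), n_term = integer(),
                  overlap = integer(), p = double(), fdr = double(),
                  significant = logical(), genes = list()))
  }
  rows <- purrr::imap(term_map, function(genes, term) {
    genes <- unique(genes)
    ov <- intersect(geneset, genes)
    tibble(term = term, n_term = length(genes), overlap = length(ov),
           p = hypergeometric_overlap(unique(geneset), genes, n_univ),
           genes = list(ov))
  })
  out <- bind_rows(rows[order(names(term_map))])
  out$fdr <- bh_adjust(out$p)
  out$significant <- out$fdr < fdr
  arrange(out, .data$fdr, .data$p, .data$term)[
    , c("term", "n_term", "overlap", "p", "fdr", "significant", "genes")]
}

#' Trace module gene flow between timepoints
#'
#' For each (from-module, to-module) pair across two partitions, counts the
#' shared genes; the flow fraction is `shared / |to module|` (normalized by
#' the later module, matching "x% of genes in the later module were shared").
#' Unassigned genes (label 0) are excluded; zero-share pairs are omitted.
#'
#' @param partition_from,partition_to Partition tibbles (`gene_id`,
#'   `module`), possibly over different gene sets.
#' @param label_from,label_to Prefixes for module names (e.g. `"M8-"`,
#'   `"M12-"`).
#' @return Tibble `from`, `to`, `shared`, `to_size`, `fraction`.
#' @export
trace_module_flow <- function(partition_from, partition_to,
                              label_from = "from_", label_to = "to_") {
  pf <- filter(partition_from, .data$module > 0)
  pt_ <- filter(partition_to, .data$module > 0)
  to_sizes <- count(pt_, .data$module, name = "to_size")
  shared <- inner_join(select(pf, "gene_id", from_module = "module"),
                       select(pt_, "gene_id", to_module = "module"),
                       by = "gene_id")
  if (nrow(shared) == 0) {
    return(tibble(from = character(), to = character(), shared = integer(),
                  to_size = integer(), fraction = double()))
  }
  flows <- count(shared, .data$from_module, .data$to_module, name = "shared")
  flows <- left_join(flows, to_sizes, by = c(to_module = "module"))
  tibble(
    from = paste0(label_from, flows$from_module),
    to = paste0(label_to, flows$to_module),
    shared = flows$shared,
    to_size = flows$to_size,
    fraction = flows$shared / flows$to_size
  )
}

#' Detect module split and merge events
#'
#' A split is one from-module contributing at least `min_fraction` to two or
#' more to-modules; a merge is one to-module receiving at least
#' `min_fraction` from two or more from-modules.
#'
#' @param flows Flow tibble from [trace_module_flow()].
#' @param min_fraction Minimum flow fraction to count a chord (default 0.1).
#' @return Tibble `event` (`split`/`merge`), `module`, `partners`
#'   (list-column).
#' @export
detect_split_merge <- function(flows, min_fraction = 0.1) {
  big <- filter(flows, .data$fraction >= min_fraction)
  splits <- big |> group_by(.data$from) |>
    summarise(n = n(), partners = list(.data$to), .groups = "drop") |>
    filter(.data$n >= 2)
  merges <- big |> group_by(.data$to) |>
    summarise(n = n(), partners = list(.data$from), .groups = "drop") |>
    filter(.data$n >= 2)
  bind_rows(
    tibble(event = rep("split", nrow(splits)), module = splits$from,
           partners = splits$partners),
    tibble(event = rep("merge", nrow(merges)), module = merges$to,
           partners = merges$partners)
  )
}

#' Assemble the tiered regulatory network
#'
#' Tier 1: the regulator TFs. Tier 2: genes that are both direct targets
#' (bound + differentially expressed) and module hubs (kME > 0.8). Tier 3:
#' remaining members of modules containing a tier-2 node. Heavy edges carry
#' binding evidence (TF to tier-2 target, and TF to TF where bound); light
#' edges connect tier-2 hubs to coexpressed tier-3 members of their module.
#'
#' @param tfs Character vector of TF names (tier 1).
#' @param direct_targets Named list per TF of direct-target gene ids.
#' @param hubs Membership tibble from [module_membership()] (needs
#'   `gene_id`, `module`, `hub`).
#' @param partition Partition tibble (`gene_id`, `module`).
#' @return Object of class `regulatory_network`: list with `nodes`
#'   (`id`, `tier`, `module`) and `edges` (`source`, `target`, `class`).
#' @export
build_hierarchical_network <- function(tfs, direct_targets, hubs,
                                       partition) {
  known_modules <- unique(partition$module)
  if (!all(hubs$module %in% c(known_modules, NA))) {
    abort("hub references a module absent from the partition")
  }
  hub_ids <- hubs$gene_id[hubs$hub]
  all_targets <- unique(unlist(direct_targets))
  tier2 <- setdiff(intersect(all_targets, hub_ids), tfs)
  t2_module <- partition$module[match(tier2, partition$gene_id)]
  mods <- unique(t2_module[!is.na(t2_module) & t2_module > 0])
  tier3 <- setdiff(
    partition$gene_id[partition$module %in% mods], c(tier2, tfs))
  nodes <- bind_rows(
    tibble(id = tfs, tier = 1L,
           module = partition$module[match(tfs, partition$gene_id)]),
    tibble(id = tier2, tier = 2L, module = t2_module),
    tibble(id = tier3, tier = 3L,
           module = partition$module[match(tier3, partition$gene_id)])
  )
  heavy <- purrr::imap(direct_targets, function(tg, tf) {
    tg <- intersect(tg, c(tier2, tfs))
    if (length(tg) == 0) return(NULL)
    tibble(source = tf, target = tg, class = "heavy")
  })
  light <- purrr::map(seq_along(tier2), function(i) {
    members <- setdiff(
      partition$gene_id[partition$module == t2_module[i]], c(tier2, tfs))
    if (length(members) == 0) return(NULL)
    tibble(source = tier2[i], target = members, class = "light")
  })
  edges <- bind_rows(c(heavy, light))
  if (nrow(edges) == 0) {
    edges <- tibble(source = character(), target = character(),
                    class = character())
  }
  structure(list(nodes = nodes, edges = edges),
            class = "regulatory_network")
}

#' @export
print.regulatory_network <- function(x, ...) {
  cat("Regulatory network: ", nrow(x$nodes), " nodes (",
      sum(x$nodes$tier == 1), " TFs, ", sum(x$nodes$tier == 2),
      " target hubs, ", sum(x$nodes$tier == 3), " members), ",
      nrow(x$edges), " edges (", sum(x$edges$class == "heavy"),
      " heavy)\n", sep = "")
  invisible(x)
}

#' @export
tidy.regulatory_network <- function(x, ...) x$edges

#' @export
glance.regulatory_network <- function(x, ...) {
  tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges),
         n_tier1 = sum(x$nodes$tier == 1), n_tier2 = sum(x$nodes$tier == 2),
         n_tier3 = sum(x$nodes$tier == 3),
         n_heavy = sum(x$edges$class == "heavy"),
         n_light = sum(x$edges$class == "light"))
}

#' Export / import a regulatory network as tables
#'
#' Writes Cytoscape-style node (`id`, `tier`, `module`) and edge (`source`,
#' `target`, `class`) TSVs; [read_network()] reproduces the graph.
#'
#' @param network A `regulatory_network`.
#' @param node_path,edge_path Output paths.
#' @return `node_path`, invisibly.
#' @export
export_network <- function(network, node_path, edge_path) {
  readr::write_tsv(network$nodes, node_path, progress = FALSE)
  readr::write_tsv(network$edges, edge_path, progress = FALSE)
  invisible(node_path)
}

#' @rdname export_network
#' @export
read_network <- function(node_path, edge_path) {
  nodes <- readr::read_tsv(node_path, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(
                             id = readr::col_character(),
                             tier = readr::col_integer(),
                             module = readr::col_integer()))
  edges <- readr::read_tsv(edge_path, show_col_types = FALSE,
                           progress = FALSE,
                           col_types = readr::cols(.default =
                                                     readr::col_character()))
  structure(list(nodes = nodes, edges = edges),
            class = "regulatory_network")
}
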