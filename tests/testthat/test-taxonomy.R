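test_that("a minimal well-formed tree loads with the expected structure", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\tparent_id\trank\tname",
               "1\t\tdomain\troot",
               "2\t1\tgenus\tg",
               "3\t2\tspecies\ts"), path)
  tree <- load_taxonomy(path)
  expect_s3_class(tree, "taxonomy_tree")
  expect_equal(nrow(tree$nodes), 3L)
  expect_equal(tree$root_id, 1L)
})

test_that("structural defects are rejected with informative errors", {
  cyc <- data.frame(taxon_id = c(1, 5, 6), parent_id = c(NA, 6, 5),
                    rank = "species")
  expect_error(taxonomy_tree(cyc), class = "rescuerank_structure_error")
  expect_error(taxonomy_tree(cyc), "cyclic")

  dangling <- data.frame(taxon_id = c(1, 2), parent_id = c(NA, 99),
                         rank = "species")
  expect_error(taxonomy_tree(dangling), "dangling",
               class = "rescuerank_structure_error")

  dup <- data.frame(taxon_id = c(1, 2, 2), parent_id = c(NA, 1, 1),
                    rank = "species")
  expect_error(taxonomy_tree(dup), "duplicate",
               class = "rescuerank_structure_error")

  two_roots <- data.frame(taxon_id = c(1, 2), parent_id = c(NA, NA),
                          rank = "domain")
  expect_error(taxonomy_tree(two_roots), "exactly one root",
               class = "rescuerank_structure_error")
})

test_that("unknown ranks are coerced to no_rank with a warning", {
  nodes <- data.frame(taxon_id = 1:2, parent_id = c(NA, 1),
                      rank = c("domain", "subspecies"))
  expect_warning(tree <- taxonomy_tree(nodes), "no_rank")
  expect_equal(tree$nodes$rank[2], "no_rank")
})

test_that("NCBI-taxdump-style tables load with node count equal to rows", {
  set.seed(42)
  nodes <- random_tree_nodes(20)
  nodes_path <- withr::local_tempfile(fileext = ".dmp")
  names_path <- withr::local_tempfile(fileext = ".dmp")
  # taxdump dialect: root is self-parenting, superkingdom plays domain
  rank_out <- ifelse(nodes$rank == "domain", "superkingdom",
                     sub("_", " ", nodes$rank))
  parent_out <- ifelse(is.na(nodes$parent_id), nodes$taxon_id,
                       nodes$parent_id)
  writeLines(paste0(nodes$taxon_id, "\t|\t", parent_out, "\t|\t",
                    rank_out, "\t|"), nodes_path)
  writeLines(paste0(nodes$taxon_id, "\t|\t", nodes$name,
                    "\t|\t\t|\tscientific name\t|"), names_path)
  tree <- load_taxonomy(nodes_path, names_path)
  expect_equal(nrow(tree$nodes), 20L)
  expect_equal(sum(tree$nodes$rank == "domain"), 2L)
  expect_equal(tree$nodes$name[tree$nodes$taxon_id == 5], "n5")
})

test_that("lineage fallback walks upward and errors on exhaustion", {
  tree <- taxonomy_tree(small_two_domain_nodes())
  in_tree <- resolve_with_fallback(tree, 6)
  expect_equal(in_tree$node$taxon_id, 6L)
  expect_equal(in_tree$fallback_steps, 0L)

  absent <- resolve_with_fallback(tree, 99, lineage = c(6, 4, 2, 1))
  expect_equal(absent$node$taxon_id, 6L)
  expect_equal(absent$fallback_steps, 1L)

  deeper <- resolve_with_fallback(tree, 99, lineage = c(98, 97, 4))
  expect_equal(deeper$node$taxon_id, 4L)
  expect_equal(deeper$fallback_steps, 3L)

  expect_error(resolve_with_fallback(tree, 99, lineage = c(98, 97)),
               class = "rescuerank_unresolvable_taxon")
})

test_that("penalized distance handles identity, siblings and domains", {
  tree <- taxonomy_tree(small_two_domain_nodes())
  sched <- unit_schedule()

  same <- penalized_distance(tree, 6, 6, sched)
  expect_equal(same$raw_distance, 0)
  expect_equal(same$path, 6L)
  expect_false(same$crossed_domain)

  sib <- penalized_distance(tree, 6, 7, sched)
  expect_equal(sib$raw_distance, 2)  # up into genus 4, down into species 7
  expect_equal(sib$path, c(6L, 4L, 7L))

  # crossing from species 6 (domain 2) to species 8 (domain 3): the
  # surcharge is added exactly once on top of the traversal cost
  cheap <- penalized_distance(tree, 6, 8, unit_schedule(crossing = 1))
  dear <- penalized_distance(tree, 6, 8, unit_schedule(crossing = 10))
  expect_true(cheap$crossed_domain)
  expect_equal(dear$raw_distance - cheap$raw_distance, 9)
  expect_error(penalized_distance(tree, 6, 99),
               class = "rescuerank_unresolvable_taxon")
})

test_that("distances match the igraph oracle, are symmetric and zero on the diagonal", {
  skip_if_not_installed("igraph")
  set.seed(101)
  for (rep in 1:4) {
    nodes <- random_tree_nodes(sample(10:60, 1), n_domains = sample(1:3, 1))
    tree <- taxonomy_tree(nodes)
    sched <- penalty_schedule()
    ids <- sample(nodes$taxon_id, min(8, nrow(nodes)))
    for (a in ids) {
      for (b in ids) {
        d <- penalized_distance(tree, a, b, sched)
        expect_equal(d$raw_distance, oracle_igraph(nodes, a, b, sched),
                     tolerance = 1e-12)
        expect_equal(d$raw_distance,
                     penalized_distance(tree, b, a, sched)$raw_distance)
        if (a == b) expect_equal(d$raw_distance, 0)
      }
    }
  }
})

test_that("raising any rank penalty never decreases a distance", {
  set.seed(202)
  nodes <- random_tree_nodes(40)
  tree <- taxonomy_tree(nodes)
  base <- penalty_schedule()
  pairs <- replicate(30, sample(nodes$taxon_id, 2), simplify = FALSE)
  for (rank in c("species", "genus", "class", "phylum")) {
    per <- base$per_rank_penalty
    per[rank] <- per[rank] + 5
    raised <- penalty_schedule(per_rank_penalty = per,
                               domain_crossing_penalty = 16)
    for (p in pairs) {
      d0 <- penalized_distance(tree, p[1], p[2], base)$raw_distance
      d1 <- penalized_distance(tree, p[1], p[2], raised)$raw_distance
      expect_gte(d1, d0)
    }
  }
})

test_that("concatenated walks through an intermediate are never shorter", {
  set.seed(303)
  nodes <- random_tree_nodes(30)
  tree <- taxonomy_tree(nodes)
  sched <- penalty_schedule()
  for (i in 1:25) {
    ids <- sample(nodes$taxon_id, 3)
    direct <- penalized_distance(tree, ids[1], ids[2], sched)$raw_distance
    via <- penalized_distance(tree, ids[1], ids[3], sched)$raw_distance +
      penalized_distance(tree, ids[3], ids[2], sched)$raw_distance
    expect_gte(via + 1e-9, direct)
  }
})

test_that("max_distance is the penalized diameter and bounds all pairs", {
  single <- taxonomy_tree(data.frame(taxon_id = 1, parent_id = NA,
                                     rank = "species"))
  expect_equal(max_distance(single), 1.0)
  expect_equal(max_distance(single, floor = 2.5), 2.5)

  # 7-node two-domain tree, unit penalties: exhaustive leaf-pair diameter
  nodes <- data.frame(
    taxon_id = 1:7, parent_id = c(NA, 1, 1, 2, 2, 3, 3),
    rank = c("no_rank", "domain", "domain", rep("species", 4))
  )
  tree <- taxonomy_tree(nodes)
  sched <- unit_schedule(crossing = 1)
  leaves <- 4:7
  brute <- max(apply(utils::combn(leaves, 2), 2, function(p) {
    penalized_distance(tree, p[1], p[2], sched)$raw_distance
  }))
  expect_equal(max_distance(tree, sched), brute)

  set.seed(404)
  nodes <- random_tree_nodes(80)
  tree <- taxonomy_tree(nodes)
  md <- max_distance(tree)
  for (i in 1:100) {
    p <- sample(nodes$taxon_id, 2)
    expect_gte(md, penalized_distance(tree, p[1], p[2])$raw_distance)
  }
})

test_that("the diameter heuristic on large trees still bounds sampled pairs", {
  set.seed(505)
  nodes <- random_tree_nodes(120)
  tree <- taxonomy_tree(nodes)
  md <- max_distance(tree, exact_limit = 50L)  # force the heuristic path
  leaves <- nodes$taxon_id[!(nodes$taxon_id %in% nodes$parent_id)]
  for (i in 1:100) {
    p <- sample(leaves, 2)
    expect_gte(md, penalized_distance(tree, p[1], p[2])$raw_distance)
  }
})

test_that("penalty schedules validate and load from config files", {
  expect_error(penalty_schedule(domain_crossing_penalty = 2),
               class = "rescuerank_config_error")  # below max per-rank
  expect_error(penalty_schedule(missing_lineage_decrement = -1),
               class = "rescuerank_config_error")

  path <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# custom schedule", "genus = 4",
               "domain_crossing_penalty = 32",
               "missing_lineage_decrement = 0.1"), path)
  sched <- read_penalty_schedule(path)
  expect_equal(unname(sched$per_rank_penalty["genus"]), 4)
  expect_equal(sched$domain_crossing_penalty, 32)
  expect_equal(sched$missing_lineage_decrement, 0.1)
  expect_equal(unname(sched$per_rank_penalty["species"]), 1)
})
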