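# Reciprocal-best-hit EC transfer and single-linkage paralog
# clustering, checked against exhaustive-search oracles and
# hand-constructed graph topologies.

make_db <- function(seqs, ecs) {
  enzyme_db(seq_set(seqs, "protein"), ec_numbers = ecs,
            function_name = sprintf("enzyme %s", names(seqs)))
}

test_that("enzyme_db validates EC syntax and annotation presence", {
  s <- c(E1 = paste(rep("MKVLAAGHKW", 10), collapse = ""))
  expect_silent(make_db(s, list("1.2.3.4")))
  expect_silent(make_db(s, list(c("1.2.3.4", "2.7.1.-"))))
  expect_error(make_db(s, list("1.2.3")), "malformed")
  expect_error(make_db(s, list("a.b.c.d")), "malformed")
  expect_error(enzyme_db(seq_set(s, "protein"), ec_numbers = list(character(0)),
                         function_name = ""),
               "neither EC nor function")
})

test_that("best_hits picks the highest-scoring target deterministically", {
  set.seed(11)
  anc <- rand_protein(150)
  far <- rand_protein(150)
  targets <- seq_set(c(t_good = anc, t_bad = far), "protein")
  queries <- seq_set(c(q1 = mutate_protein(anc, 0.9)), "protein")
  bh <- best_hits(queries, targets)
  expect_identical(bh$target_id, "t_good")
  # score ties break toward the lexicographically smallest target id
  targets2 <- seq_set(c(t_b = anc, t_a = anc), "protein")
  bh2 <- best_hits(queries, targets2)
  expect_identical(bh2$target_id, "t_a")
  # queries without a qualifying hit are absent
  hopeless <- seq_set(c(q2 = "MKVLA"), "protein")
  expect_identical(nrow(best_hits(hopeless, targets)), 0L)
})

test_that("best_hits agrees with an exhaustive argmax oracle", {
  set.seed(202)
  sch <- scoring_scheme("protein")
  for (rep in 1:5) {
    anc <- replicate(3, rand_protein(100))
    targets <- setNames(vapply(rep(anc, 2), mutate_protein, character(1),
                               identity = 0.85),
                        sprintf("t%02d", 1:6))
    queries <- setNames(vapply(sample(anc, 4, TRUE), mutate_protein,
                               character(1), identity = 0.8),
                        sprintf("q%02d", 1:4))
    tset <- seq_set(targets, "protein"); qset <- seq_set(queries, "protein")
    got <- best_hits(qset, tset, sch, evalue_max = 1e-3)
    for (q in names(queries)) {
      rows <- do.call(rbind, lapply(names(targets), function(t)
        local_align(qset[q], tset[t], sch)))
      rows <- rows[rows$score > 0 & rows$evalue <= 1e-3, , drop = FALSE]
      want <- rows[order(-rows$score, rows$subject_id), ][1, ]
      expect_identical(got$target_id[got$query_id == q], want$subject_id)
      expect_equal(got$score[got$query_id == q], want$score)
    }
  }
})

test_that("reciprocal best hits require agreement in both directions", {
  set.seed(77)
  anc <- rand_protein(200)
  # q_near is the db entry itself; q_far a distant mutant. The db entry's
  # best hit is q_near, so (q_far, ENZ) is not reciprocal even though
  # ENZ is q_far's best (and only) hit.
  prots <- seq_set(c(q_far = mutate_protein(anc, 0.7),
                     q_near = anc), "protein")
  db_seqs <- seq_set(c(ENZ = anc), "protein")
  rbh <- reciprocal_best_hits(prots, db_seqs)
  expect_identical(rbh$orf_id, "q_near")
  expect_identical(rbh$accession, "ENZ")
})

test_that("transfer_ec carries all ECs of the matched entry", {
  seqs <- c(E1 = paste(rep("MKVLAAGHKW", 12), collapse = ""))
  db <- make_db(seqs, list(c("1.1.1.1", "2.7.1.30")))
  pairs <- data.frame(orf_id = "orfA", accession = "E1",
                      score = 100, evalue = 1e-20, pident = 0.9)
  asg <- transfer_ec(pairs, db)
  expect_identical(asg$ec_numbers[[1]], c("1.1.1.1", "2.7.1.30"))
  expect_identical(asg$provenance, "rbh_direct")
  expect_identical(asg$best_hit_accession, "E1")
  bad <- data.frame(orf_id = "orfA", accession = "NOPE",
                    score = 1, evalue = 1, pident = 0)
  expect_error(transfer_ec(bad, db), "NOPE")
})

test_that("identical proteins cluster together; unrelated ones do not", {
  set.seed(13)
  a <- rand_protein(120); b <- rand_protein(120)
  prots <- seq_set(c(x1 = a, x2 = a, x3 = a, y1 = b), "protein")
  cl <- cluster_paralogs(prots)
  expect_identical(length(unique(cl$cluster_id)), 2L)
  expect_identical(length(unique(cl$cluster_id[cl$orf_id != "y1"])), 1L)
  expect_false(cl$cluster_id[cl$orf_id == "y1"] %in%
                 cl$cluster_id[cl$orf_id != "y1"])
})

test_that("single linkage chains through intermediates", {
  set.seed(41)
  b <- rand_protein(150)
  a <- mutate_protein(b, 0.55)
  cc <- mutate_protein(b, 0.55)
  prots <- seq_set(c(a = a, b = b, c = cc), "protein")
  sch <- scoring_scheme("protein")
  edges <- explicit_edges(prots, sch)
  key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
  # a-b and b-c pass the 35%/70% edge rule by construction
  expect_true(all(c("a b", "b c") %in% key))
  cl <- cluster_paralogs(prots, sch)
  expect_identical(length(unique(cl$cluster_id)), 1L)
})

test_that("clusters equal brute-force components of the explicit edges", {
  set.seed(303)
  sch <- scoring_scheme("protein")
  for (rep in 1:4) {
    anc <- replicate(2, rand_protein(90))
    seqs <- c(vapply(rep(anc, each = 3), mutate_protein, character(1),
                     identity = 0.7),
              replicate(3, rand_protein(90)))
    names(seqs) <- sprintf("s%02d", seq_along(seqs))
    prots <- seq_set(seqs, "protein")
    cl <- cluster_paralogs(prots, sch)
    comp <- brute_force_components(names(prots), explicit_edges(prots, sch))
    got <- split(cl$orf_id, cl$cluster_id)
    want <- split(names(comp), comp)
    canon <- function(p) unname(lapply(p, sort))[order(vapply(p, min, ""))]
    expect_identical(canon(got), canon(want))
  }
})

test_that("clustering is invariant to input order", {
  set.seed(55)
  anc <- rand_protein(100)
  seqs <- setNames(c(vapply(1:4, function(i) mutate_protein(anc, 0.7),
                            character(1)),
                     replicate(3, rand_protein(100))),
                   sprintf("p%d", 1:7))
  cl1 <- cluster_paralogs(seq_set(seqs, "protein"))
  cl2 <- cluster_paralogs(seq_set(rev(seqs), "protein"))
  cl2 <- cl2[match(cl1$orf_id, cl2$orf_id), ]
  expect_identical(cl1$cluster_id, unname(cl2$cluster_id))
})

test_that("propagation annotates whole clusters and flags disagreement", {
  clusters <- data.frame(orf_id = c("a", "b", "c", "d", "e"),
                         cluster_id = c(1L, 1L, 1L, 2L, 3L))
  direct <- data.frame(
    orf_id = c("a", "b", "d"),
    ec_numbers = I(list("1.1.1.1", c("1.1.1.1", "4.2.1.11"), "2.7.1.1")),
    function_name = c("fnA", "fnB", "fnD"),
    provenance = "rbh_direct",
    best_hit_accession = c("E1", "E2", "E3"),
    cluster_id = NA_integer_, stringsAsFactors = FALSE)
  out <- propagate_ec(clusters, direct)
  # c inherits the union of its cluster's direct ECs
  crow <- out[out$orf_id == "c", ]
  expect_identical(crow$provenance, "paralog_propagated")
  expect_identical(crow$ec_numbers[[1]], c("1.1.1.1", "4.2.1.11"))
  expect_true(crow$ambiguous_cluster)      # a and b disagree
  expect_false(out$ambiguous_cluster[out$orf_id == "d"])
  # e's cluster has no direct member: never annotated
  expect_false("e" %in% out$orf_id)
  # direct assignments pass through unchanged
  expect_identical(out$ec_numbers[out$orf_id == "a"][[1]], "1.1.1.1")
  expect_identical(out$provenance[out$orf_id == "a"], "rbh_direct")
  expect_setequal(out$orf_id, c("a", "b", "c", "d"))
})

test_that("end-to-end annotation recovers a small planted family", {
  set.seed(500)
  anc <- rand_protein(180)
  db <- make_db(c(ENZ1 = anc), list("1.2.3.4"))
  prots <- seq_set(c(m1 = mutate_protein(anc, 0.85),
                     m2 = mutate_protein(anc, 0.85),
                     junk = rand_protein(180)), "protein")
  ann <- annotate_enzymes(prots, db)
  asg <- ann$assignments
  expect_setequal(asg$orf_id, c("m1", "m2"))
  expect_true(all(vapply(asg$ec_numbers, identical, TRUE, "1.2.3.4")))
  expect_false("junk" %in% asg$orf_id)
  # serialization keeps one row per assignment with joined ECs
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ec_assignments(asg, path)
  back <- read.delim(path, stringsAsFactors = FALSE)
  expect_identical(back$ec_numbers, rep("1.2.3.4", 2))
})
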