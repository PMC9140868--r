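# Seed-and-extend search against the exhaustive Smith-Waterman oracle,
# plus chaining, gene location and the presence matrix.

test_that("a verbatim planted query is found with identity and cover 1", {
  set.seed(501)
  q <- random_dna(300)
  s <- plant_at(random_dna(2000), 701, q)
  h <- local_search(q, c(subj = s))
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1)
  expect_equal(h$query_cover, 1)
  expect_equal(h$sstart, 701L)
  expect_equal(h$send, 1000L)
  expect_false(h$partial)
})

test_that("a 10%-substituted copy is found near 0.90 identity, not partial", {
  set.seed(502)
  q <- random_dna(400)
  copy <- q
  pos <- sample(6:395, 40)
  ch <- strsplit(copy, "")[[1]]
  ch[pos] <- vapply(ch[pos], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
  copy <- paste(ch, collapse = "")
  s <- plant_at(random_dna(3000), 1001, copy)
  h <- local_search(q, c(subj = s))
  expect_gt(h$identity[1], 0.85)
  expect_lt(h$identity[1], 0.95)
  expect_false(h$partial[1])
})

test_that("an end-truncated copy is flagged partial with span query cover", {
  set.seed(503)
  q <- random_dna(923)
  frag <- substring(q, 398, 923)
  s <- paste0(frag, random_dna(1255 - nchar(frag)))
  h <- local_search(q, c(scafX = s))
  expect_true(h$partial[1])
  expect_equal(h$query_cover[1], 526 / 923, tolerance = 0.01)
  expect_equal(h$qstart[1], 398L)
  expect_equal(h$qend[1], 923L)
})

test_that("best hit equals the exhaustive Smith-Waterman oracle", {
  for (seed in 1:8) {
    set.seed(600 + seed)
    qlen <- sample(200:800, 1)
    q <- random_dna(qlen)
    copy <- q
    n_mut <- floor(stats::runif(1, 0, 0.08) * qlen)
    if (n_mut > 0) {
      pos <- sample(6:(qlen - 5), n_mut)
      ch <- strsplit(copy, "")[[1]]
      ch[pos] <- vapply(ch[pos], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
      copy <- paste(ch, collapse = "")
    }
    slen <- sample(3000:10000, 1)
    at <- sample(slen - qlen - 10L, 1)
    s <- plant_at(random_dna(slen), at, copy)
    got <- local_search(q, c(subj = s))[1, ]
    want <- sw_oracle(q, s)
    expect_equal(got$score, want$score)
    expect_equal(got$qstart, want$qstart)
    expect_equal(got$qend, want$qend)
    expect_equal(got$sstart, want$sstart)
    expect_equal(got$send, want$send)
  }
})

test_that("a reverse-complemented copy is found on the minus strand with equal identity", {
  set.seed(504)
  q <- random_dna(350)
  s_plus <- plant_at(random_dna(2500), 901, q)
  s_minus <- plant_at(random_dna(2500), 901, revcomp(q))
  hp <- local_search(q, c(s = s_plus))
  hm <- local_search(q, c(s = s_minus))
  expect_equal(hm$strand[1], "-")
  expect_equal(hm$identity[1], hp$identity[1])
  expect_equal(hm$score[1], hp$score[1])
  expect_equal(hm$sstart[1], 901L)
})

test_that("raising min_identity never increases the number of hits", {
  set.seed(505)
  q <- random_dna(300)
  s <- random_dna(4000)
  for (at in c(301, 1501, 3001)) {
    copy <- q
    pos <- sample(6:295, sample(10:60, 1))
    ch <- strsplit(copy, "")[[1]]
    ch[pos] <- vapply(ch[pos], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1), character(1))
    s <- plant_at(s, at, paste(ch, collapse = ""))
  }
  n_hits <- vapply(c(0.5, 0.7, 0.85, 0.95, 0.999),
                   function(mi) nrow(local_search(q, c(s = s),
                                                  min_identity = mi)),
                   integer(1))
  expect_true(all(diff(n_hits) <= 0L))
})

test_that("chaining reassembles a copy split by a large interior deletion", {
  set.seed(506)
  q <- random_dna(2000)
  # subject copy = query minus 1200 bp from the middle
  copy <- paste0(substring(q, 1, 400), substring(q, 1601, 2000))
  s <- plant_at(random_dna(3000), 1001, copy)
  h <- local_search(q, c(subj = s))
  expect_gte(nrow(h), 2L)
  reg <- chain_hits(h)
  expect_equal(nrow(reg), 1L)
  expect_equal(reg$subject_span, 800L)
  expect_equal(reg$query_cover, 1, tolerance = 0.01)
  expect_false(reg$partial)
})

test_that("locate_gene labels planted, diverged, and absent genes", {
  set.seed(507)
  exons <- Biostrings::DNAStringSet(c(e1 = random_dna(150),
                                      e2 = random_dna(200)))
  z <- plant_at(plant_at(random_dna(3000), 501, as.character(exons[[1]])),
                1501, as.character(exons[[2]]))
  dec <- random_dna(2500)
  for (i in 1:2) {
    cp <- zwmarkers:::.apply_divergence(as.character(exons[[i]]), 0.08)
    dec <- plant_at(dec, 300 + 900 * (i - 1), cp)
  }
  asm <- Biostrings::DNAStringSet(c(chrZ = z, s37 = dec, chrW = random_dna(2000)))
  roles <- role_map(c(chrZ = "Z", s37 = "scaffold", chrW = "W"))
  loc <- locate_gene(exons, asm, roles)
  expect_equal(loc$role[1], "Z")
  expect_equal(loc$role, c("Z", "scaffold"))
  absent <- locate_gene(Biostrings::DNAStringSet(c(x = random_dna(180))),
                        asm, roles)
  expect_equal(nrow(absent), 0L)
})

test_that("presence matrix agrees with locate_gene and counts planted genes", {
  set.seed(508)
  g1 <- Biostrings::DNAStringSet(c(a = random_dna(150)))
  g2 <- Biostrings::DNAStringSet(c(b = random_dna(150)))
  g3 <- Biostrings::DNAStringSet(c(c = random_dna(150)))
  z <- random_dna(2000)
  z <- plant_at(z, 101, as.character(g1[[1]]))
  z <- plant_at(z, 601, as.character(g2[[1]]))
  w <- plant_at(random_dna(1500), 501, as.character(g2[[1]]))
  asm <- Biostrings::DNAStringSet(c(chrZ = z, chrW = w))
  roles <- role_map(c(chrZ = "Z", chrW = "W"))
  pm <- presence_matrix(list(g1 = g1, g2 = g2, g3 = g3), asm, roles)
  expect_equal(unname(rowSums(pm$present)), c(1L, 2L, 0L))
  expect_equal(unname(colSums(pm$present)), c(2L, 1L))
  for (gn in rownames(pm$present)) {
    loc <- locate_gene(get(gn), asm, roles)
    expect_setequal(loc$subject_id,
                    colnames(pm$present)[pm$present[gn, ]])
  }
  empty <- presence_matrix(list(), asm, roles)
  expect_equal(nrow(empty$present), 0L)
})
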