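test_that("FASTA headers parse into records with metadata", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(
    ">p1|Ectocarpus siliculosus|ochrophyta|PEPC", "MKVAAQNTG",
    ">p2|Chondrus crispus|rhodophyta", "mardelk*",
    ">p3|Galdieria sulphuraria|rhodophyta|PCK", "MTTTK"
  ), path)
  ps <- read_fasta(path)
  expect_s3_class(ps, "protein_set")
  expect_equal(nrow(ps), 3L)
  expect_equal(ps$id, c("p1", "p2", "p3"))           # order preserved
  expect_equal(ps$taxon_group[1], "ochrophyta")
  expect_equal(ps$enzyme_label[1], "PEPC")
  expect_true(is.na(ps$enzyme_label[2]))
  expect_equal(ps$residues[2], "MARDELK")            # upper-cased, stop stripped
  expect_true(ps$had_stop[2])
})

test_that("FASTA errors and warnings follow the header contract", {
  path <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p2|X|martian", "MKV"), path)
  expect_warning(ps <- read_fasta(path), "martian")
  expect_equal(ps$taxon_group, "other")

  writeLines(c(">only_id", "MKV"), path)
  expect_error(read_fasta(path), "line 1")

  writeLines(c(">p1|org|other", "MKV", ">p2|org", "MRT"), path)
  expect_error(read_fasta(path), "line 3")
})

test_that("FASTA round-trips byte-stably", {
  ps <- gen_protein_family(
    motif_plant_spec("PEPC", length = 40, planted_terminal = "QNTG",
                     mutation_rate = 0.1, seed = 7),
    n = 5, taxon_group = "rhodophyta"
  )
  f1 <- withr::local_tempfile(fileext = ".fasta")
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ps, f1)
  back <- read_fasta(f1)
  expect_equal(as.data.frame(back), as.data.frame(ps))
  write_fasta(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("read filter discards on strict 'more than' thresholds only", {
  mk <- function(n_low, n_n, len = 100L) {
    q <- rep(35L, len); if (n_low > 0) q[seq_len(n_low)] <- 19L
    b <- rep("A", len); if (n_n > 0) b[seq.int(len - n_n + 1L, len)] <- "N"
    list(b = paste(b, collapse = ""), q = q)
  }
  r1 <- mk(11, 0)   # 11% low quality -> discarded
  r2 <- mk(10, 5)   # exactly at both bounds -> kept
  r3 <- mk(0, 3, 40L)  # 7.5% N -> discarded
  reads <- read_set(c("r1", "r2", "r3"),
                    c(r1$b, r2$b, r3$b), list(r1$q, r2$q, r3$q))
  res <- filter_reads(reads)
  expect_equal(res$kept$id, "r2")
  expect_equal(res$n_discarded, 2L)
  expect_equal(nrow(res$kept) + res$n_discarded, nrow(reads))

  # idempotence: refiltering the kept set discards nothing
  res2 <- filter_reads(res$kept)
  expect_equal(res2$n_discarded, 0L)
  expect_equal(res2$kept$id, res$kept$id)
})

test_that("read filter extremes keep everything / drop any flaw", {
  reads <- gen_reads(20, 50, 0.1, 0.04, seed = 3)
  all_cfg <- read_filter_config(1.0, 20, 1.0)
  expect_equal(filter_reads(reads, all_cfg)$n_discarded, 0L)
  none_cfg <- read_filter_config(0.0, 20, 0.0)
  # every generated read carries >=1 low-quality base and >=1 N here
  expect_equal(filter_reads(reads, none_cfg)$n_discarded, 20L)
})

test_that("length mismatch between bases and qualities names the read", {
  expect_error(read_set("rx", "ACGT", list(c(30L, 30L))), "rx")
})

test_that("FASTQ round-trips through Phred+33", {
  reads <- gen_reads(8, 60, 0.1, 0.05, seed = 11)
  path <- withr::local_tempfile(fileext = ".fastq")
  write_fastq(reads, path)
  back <- read_fastq(path)
  expect_equal(back$id, reads$id)
  expect_equal(back$bases, reads$bases)
  expect_equal(back$quals, reads$quals)
})

test_that("Newick samples parse, enforce one leaf set, and round-trip", {
  path <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("((A,B),(C,D));", "((A,C),(B,D));"), path)
  ts <- read_newick_samples(path)
  expect_equal(length(ts), 2L)
  expect_equal(ts$leaf_set, c("A", "B", "C", "D"))

  out <- withr::local_tempfile(fileext = ".nwk")
  write_newick_samples(ts, out)
  ts2 <- read_newick_samples(out)
  expect_equal(length(ts2), 2L)
  expect_equal(vapply(ts2$trees, function(t) phangorn::RF.dist(t, ts$trees[[1]]), numeric(1)),
               vapply(ts$trees, function(t) phangorn::RF.dist(t, ts$trees[[1]]), numeric(1)))

  writeLines(c("((A,B),(C,D));", "((A,B),(C,E));"), path)
  expect_error(read_newick_samples(path), "tree 2")

  writeLines("((A,B),(C,D);", path)
  expect_error(read_newick_samples(path), "line 1")

  writeLines("(('A x',B),(C,D));", path)
  expect_error(read_newick_samples(path), "quoted")

  writeLines(character(), path)
  expect_equal(length(read_newick_samples(path)), 0L)
})

test_that("inventory tables read counts with blanks as zero and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "Taxonomy\tOrganism\tALT\tAST\tMDH\tME\tPCK\tPEPC\tPK\tPPDK",
    "Ochrophyta\tEctocarpus siliculosus\t1\t3\t2\t2\t1\t1\t3\t1",
    "Chlorophyta\tBathycoccus prasinos\t\t\t\t\t\t\t\t1",
    "Rhodophyta\tEmpty organism\t\t\t\t\t\t\t\t"
  ), path)
  inv <- read_inventory(path)
  expect_equal(sum(inv["Ectocarpus siliculosus", ] >= 1L), 8L)
  expect_equal(sum(inv["Bathycoccus prasinos", ] != 0L), 1L)
  expect_equal(inv["Bathycoccus prasinos", "PPDK"], 1L)
  expect_true(all(inv["Empty organism", ] == 0L))

  out <- withr::local_tempfile(fileext = ".tsv")
  write_inventory(inv, out)
  inv2 <- read_inventory(out)
  expect_equal(inv2[rownames(inv), colnames(inv)], inv[, ],
               ignore_attr = TRUE)

  writeLines(c("Taxonomy\tOrganism\tPEPC", "X\tOrg A\t-2"), path)
  expect_error(read_inventory(path), "row 1.*PEPC")
})
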