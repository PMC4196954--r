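test_that("C-terminal tetrapeptide rule separates BTPC, PTPC, unclassified", {
  cases <- list(
    list(seq = "MAVGVKQNTG", type = "PTPC", tetra = "QNTG"),
    list(seq = "MAVGAARNTG", type = "BTPC", tetra = "RNTG"),
    list(seq = "MAVGAAKNTG", type = "BTPC", tetra = "KNTG"),
    list(seq = "MAVGAAANTG", type = "unclassified", tetra = "ANTG"),
    list(seq = "MAVGKQNTG*", type = "PTPC", tetra = "QNTG")  # stop stripped first
  )
  for (cs in cases) {
    got <- classify_pepc_terminus(cs$seq)
    expect_equal(got$pepc_type, cs$type, info = cs$seq)
    expect_equal(got$terminal_tetrapeptide, cs$tetra, info = cs$seq)
  }
  expect_error(classify_pepc_terminus("KNT"), "shorter than 4")
})

test_that("the terminus verdict depends only on the last four residues", {
  set.seed(7)
  for (k in 1:20) {
    tail4 <- c("QNTG", "KNTG", "RNTG", "ANTG", "WWWW")[(k %% 5) + 1]
    short <- paste0(random_peptide(4), tail4)
    long <- paste0(random_peptide(60), short)
    expect_equal(classify_pepc_terminus(long)$pepc_type,
                 classify_pepc_terminus(short)$pepc_type)
  }
})

test_that("C4-site calls follow residue-set membership at the mapped column", {
  ref <- default_pepc_reference()
  spec <- diagnostic_site_spec()

  on_ref <- call_c4_site(ref, spec)
  expect_equal(on_ref$c4_status, "C4_type")
  expect_equal(on_ref$diagnostic_residue, "S")
  expect_equal(on_ref$diagnostic_query_pos, 774L)

  swap <- function(res, pos, letter) {
    paste0(substr(res, 1, pos - 1), letter, substr(res, pos + 1, nchar(res)))
  }
  ala <- call_c4_site(swap(ref$residues, 774, "A"), spec)
  expect_equal(ala$c4_status, "non_C4")
  expect_equal(ala$diagnostic_residue, "A")

  gly <- call_c4_site(swap(ref$residues, 774, "G"), spec)
  expect_equal(gly$c4_status, "other")

  gapped <- paste0(substr(ref$residues, 1, 765), substr(ref$residues, 785, nchar(ref$residues)))
  del <- call_c4_site(gapped, spec)
  expect_equal(del$c4_status, "undetermined")
  expect_equal(del$diagnostic_residue, "-")
  expect_true(is.na(del$diagnostic_query_pos))

  # windowed mode reports the nearest mapped in-window residue instead
  win_spec <- diagnostic_site_spec(window = 25)
  near <- call_c4_site(gapped, win_spec)
  expect_false(near$c4_status == "undetermined")
})

test_that("terminus typing and C4-site calling are independent verdicts", {
  ref <- default_pepc_reference()
  len <- nchar(ref$residues)
  mk <- function(terminal, site) {
    spec <- motif_plant_spec("PEPC", length = len, base = ref$residues,
                            planted_terminal = terminal,
                            diagnostic_residue = site, diagnostic_position = 774,
                            mutation_rate = 0.02, seed = 40 + nchar(terminal))
    gen_protein_family(spec, 1)
  }
  phaeo <- classify_pepc(mk("KNTG", "S"))  # Phaeophyceae-style BTPC, C4-type
  expect_equal(phaeo$pepc_type, "BTPC")
  expect_equal(phaeo$c4_status, "C4_type")

  diatom <- classify_pepc(mk("KNTG", "A"))  # diatom-style BTPC, non-C4
  expect_equal(diatom$pepc_type, "BTPC")
  expect_equal(diatom$c4_status, "non_C4")

  rhodo <- classify_pepc(mk("QNTG", "S"))   # rhodophyte-style PTPC
  expect_equal(rhodo$pepc_type, "PTPC")
})

test_that("PPDK/PEPS discrimination follows the signature windows", {
  ppdk_sig <- default_ppdk_signatures()[[1]]
  peps_sig <- default_peps_signatures()[[1]]
  backbone <- function(sig, pos, len = 200) {
    spec <- motif_plant_spec("PPDK", length = len, signature = sig,
                            signature_position = pos, mutation_rate = 0, seed = 3)
    gen_protein_family(spec, 1)$residues
  }

  with_ppdk <- classify_ppdk_peps(backbone(ppdk_sig$pattern, 40))
  expect_equal(with_ppdk$verdict, "PPDK")
  expect_equal(with_ppdk$matched_signatures$position, 40L)

  with_peps <- classify_ppdk_peps(backbone(peps_sig$pattern, 25))
  expect_equal(with_peps$verdict, "PEPS_like")

  both <- paste0(substr(backbone(ppdk_sig$pattern, 10), 1, 60),
                 peps_sig$pattern,
                 strrep("G", 40))
  expect_equal(classify_ppdk_peps(both)$verdict, "ambiguous")

  neither <- strrep("GA", 80)
  expect_equal(classify_ppdk_peps(neither)$verdict, "ambiguous")

  # a signature outside its N-terminal window does not count
  late <- backbone(ppdk_sig$pattern, 180)
  expect_equal(classify_ppdk_peps(late)$verdict, "ambiguous")

  expect_error(signature_spec("bad", "(((", 1, 10), "malformed")
  expect_error(classify_ppdk_peps("MKVL", list(), default_peps_signatures()),
               "non-empty")
})

test_that("planted classes are recovered perfectly at zero mutation", {
  ref <- default_pepc_reference()
  len <- nchar(ref$residues)
  site_spec <- diagnostic_site_spec()

  termini <- c(BTPC = "RNTG", BTPC = "KNTG", PTPC = "QNTG", unclassified = "ANTG")
  for (i in seq_along(termini)) {
    fam <- gen_protein_family(
      motif_plant_spec("PEPC", length = 100, planted_terminal = termini[[i]],
                       mutation_rate = 0, seed = 50 + i), n = 5)
    got <- vapply(fam$residues, function(r) classify_pepc_terminus(r)$pepc_type, character(1))
    expect_true(all(got == names(termini)[i]))
  }

  for (letter in c(C4_type = "S", non_C4 = "A")) {
    fam <- gen_protein_family(
      motif_plant_spec("PEPC", length = len, base = ref$residues,
                       diagnostic_residue = letter, diagnostic_position = 774,
                       mutation_rate = 0, seed = 60), n = 4)
    got <- vapply(fam$residues, function(r) call_c4_site(r, site_spec)$c4_status, character(1))
    expect_true(all(got == names(which(c(C4_type = "S", non_C4 = "A") == letter))))
  }

  ppdk_fam <- gen_protein_family(
    motif_plant_spec("PPDK", length = 200, signature = default_ppdk_signatures()[[1]]$pattern,
                     signature_position = 40, mutation_rate = 0, seed = 61), n = 5)
  peps_fam <- gen_protein_family(
    motif_plant_spec("PEPS", length = 200, signature = default_peps_signatures()[[1]]$pattern,
                     signature_position = 40, mutation_rate = 0, seed = 62), n = 5)
  expect_true(all(vapply(ppdk_fam$residues,
                         function(r) classify_ppdk_peps(r)$verdict, character(1)) == "PPDK"))
  expect_true(all(vapply(peps_fam$residues,
                         function(r) classify_ppdk_peps(r)$verdict, character(1)) == "PEPS_like"))
})

test_that("C4-site accuracy does not increase with mutation rate", {
  ref <- default_pepc_reference()
  len <- nchar(ref$residues)
  spec <- diagnostic_site_spec()
  acc <- vapply(c(0, 0.05, 0.1, 0.2), function(rate) {
    fam <- gen_protein_family(
      motif_plant_spec("PEPC", length = len, base = ref$residues,
                       diagnostic_residue = "S", diagnostic_position = 774,
                       mutation_rate = rate, seed = 70), n = 6)
    mean(vapply(fam$residues, function(r) call_c4_site(r, spec)$c4_status,
                character(1)) == "C4_type")
  }, numeric(1))
  expect_equal(acc[1], 1.0)
  expect_true(all(diff(acc) <= 1e-12))
})
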