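test_that("palindrome detection follows IUPAC complementation", {
  expect_true(is_palindrome("GATC"))
  expect_true(is_palindrome("RAATTY"))   # R complements Y
  expect_false(is_palindrome("CGAAT"))
  expect_true(is_palindrome("ATCGAT"))
  expect_error(is_palindrome("GAXC"), "invalid IUPAC")
})

test_that("reverse complement is an involution on random patterns", {
  set.seed(11)
  for (i in 1:25) {
    p <- random_iupac_motif()
    expect_identical(revcomp_iupac(revcomp_iupac(p)), p)
    expect_identical(revcomp_iupac(p), oracle_revcomp(p))
  }
})

test_that("motif specs validate the methylatable base and derive the
           reverse offset for palindromes", {
  m <- motif_spec("GATC", 1L, "m6A")
  expect_equal(m$meth_offset_rev, 2L)
  m <- motif_spec("RAATTY", 2L, "m6A")
  expect_equal(m$meth_offset_rev, 3L)
  expect_null(motif_spec("CGAAT", 2L, "m6A")$meth_offset_rev)
  expect_error(motif_spec("GATC", 0L, "m6A"), "incompatible")
  expect_error(motif_spec("GATC", 1L, "m5C"), "incompatible")
  expect_error(motif_spec("A", 0L, "m6A"), "length")
})

test_that("palindromic scan reports each site once with both strand
           coordinates", {
  g <- c(c1 = "AAGATCAA")
  inst <- find_motif_instances(g, motif_spec("GATC", 1L, "m6A"))
  expect_equal(nrow(inst), 1)
  expect_equal(inst$start, 2L)
  expect_equal(inst$end, 6L)
  expect_equal(inst$meth_pos_fwd, 3L)
  expect_equal(inst$meth_pos_rev, 4L)

  inst <- find_motif_instances(c(c1 = "GAATTC"),
                               motif_spec("RAATTY", 2L, "m6A"))
  expect_equal(nrow(inst), 1)   # G matches R, C matches Y

  expect_equal(nrow(find_motif_instances(c(c1 = "CCCCCC"),
                                         motif_spec("GATC", 1L, "m6A"))), 0)
})

test_that("genome N never matches any motif symbol", {
  g <- c(c1 = "AAGNTCAA")
  expect_equal(nrow(find_motif_instances(g, motif_spec("GANC", 1L, "m6A"))), 0)
  expect_equal(nrow(find_motif_instances(g, motif_spec("GNTC", 1L, "m6A"))), 0)
})

test_that("non-palindromic motifs yield strand-resolved instances", {
  # CGAAT at 0-based 1 on +; its revcomp ATTCG at 8
  g <- c(c1 = "ACGAATGGATTCGG")
  inst <- find_motif_instances(g, motif_spec("CGAAT", 3L, "m6A"))
  expect_equal(nrow(inst), 2)
  plus <- inst[inst$strand_of_match == "+", ]
  minus <- inst[inst$strand_of_match == "-", ]
  expect_equal(plus$start, 1L)
  expect_equal(plus$meth_pos_fwd, 4L)
  expect_true(is.na(plus$meth_pos_rev))
  expect_equal(minus$start, 8L)
  expect_equal(minus$meth_pos_rev, 8L + 5L - 1L - 3L)
  expect_true(is.na(minus$meth_pos_fwd))
})

test_that("scanning matches the IUPAC-expansion oracle on random inputs", {
  set.seed(42)
  for (i in 1:25) {
    seq <- random_genome_seq(sample(200:800, 1))
    pat <- random_iupac_motif()
    g <- c(c1 = seq)
    # compare forward-strand hit set against the naive oracle
    if (is_palindrome(pat)) {
      off <- which(strsplit(pat, "")[[1]] %in% c("A", "R", "W", "M", "D",
                                                 "H", "V", "N"))[1]
      if (is.na(off)) next
      inst <- find_motif_instances(g, motif_spec(pat, off - 1L, "m6A"))
      expect_equal(inst$start, oracle_scan(seq, pat))
    } else {
      offs <- which(strsplit(pat, "")[[1]] %in% c("A", "R", "W", "M", "D",
                                                  "H", "V", "N"))
      if (!length(offs)) next
      inst <- find_motif_instances(g, motif_spec(pat, offs[1] - 1L, "m6A"))
      expect_equal(inst$start[inst$strand_of_match == "+"],
                   oracle_scan(seq, pat))
      expect_equal(inst$start[inst$strand_of_match == "-"],
                   oracle_scan(seq, oracle_revcomp(pat)))
    }
  }
})

test_that("scanning a genome and its reverse complement mirrors instances", {
  set.seed(7)
  seq <- random_genome_seq(500)
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]),
              collapse = "")
  m <- motif_spec("CGAAT", 3L, "m6A")
  a <- find_motif_instances(c(c1 = seq), m)
  b <- find_motif_instances(c(c1 = rc), m)
  expect_equal(nrow(a), nrow(b))
  # a + hit at s maps to a - hit at len - end in the reverse complement
  expect_setequal(500L - a$end[a$strand_of_match == "+"],
                  b$start[b$strand_of_match == "-"])
})

test_that("motif classification partitions patterns into the four types", {
  cls <- function(p, off = NULL, mt = "m6A") {
    if (is.null(off)) {
      sym <- strsplit(p, "")[[1]]
      off <- which(vapply(sym, function(s) "A" %in% IUPAC_ORACLE[[s]],
                          logical(1)))[1] - 1L
    }
    classify_motif(motif_spec(p, off, mt))$category
  }
  expect_equal(cls("CAGNNNNNTCA"), "TypeI_bipartite")
  expect_equal(cls("GCCCAG"), "TypeIIG_like")
  expect_equal(cls("CGAAT"), "TypeIII_like")
  expect_equal(cls("GATC"), "TypeII_palindromic")
  expect_equal(cls("RAATTY"), "TypeII_palindromic")
  expect_equal(cls("TTAA"), "TypeII_palindromic")
  # degenerate symbols count as specific positions: 6 non-N => IIG
  expect_equal(cls("RYSWAC"), "TypeIIG_like")
  # total function over random motifs
  set.seed(5)
  cats <- replicate(30, {
    p <- random_iupac_motif()
    off <- which(vapply(strsplit(p, "")[[1]],
                        function(s) "A" %in% IUPAC_ORACLE[[s]],
                        logical(1)))[1] - 1L
    if (is.na(off)) NA_character_ else cls(p, off)
  })
  expect_true(all(stats::na.omit(cats) %in%
                    c("TypeI_bipartite", "TypeII_palindromic",
                      "TypeIII_like", "TypeIIG_like")))
})

test_that("mean inter-motif distance averages successive start gaps", {
  inst <- data.frame(contig_id = "c1", start = c(0L, 10L, 30L))
  expect_equal(unname(mean_intermotif_distance(inst)), 15)
  inst <- data.frame(contig_id = "c1", start = seq(0L, 900L, by = 100L))
  expect_equal(unname(mean_intermotif_distance(inst)), 100)
  set.seed(3)
  starts <- sort(sample.int(10000, 50))
  inst <- data.frame(contig_id = "c1", start = starts)
  expect_equal(unname(mean_intermotif_distance(inst)),
               mean(diff(starts)))
  expect_error(mean_intermotif_distance(inst[1, , drop = FALSE]), ">= 2")
})
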