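pp50 <- parameterPoint(P = 69, C = 50, W = 30, L = 400)

test_that("bead counts follow ceil(length / (C*W))", {
  # chromosome 1 and 4 lengths at C*W = 1500 bp per bead
  expect_equal(discretizeChromosome(230000, pp50)$n, ceiling(230000 / 1500))
  expect_equal(discretizeChromosome(230000, pp50)$n, 154)
  expect_equal(discretizeChromosome(1531000, pp50)$n, ceiling(1531000 / 1500))
  expect_equal(discretizeChromosome(1531000, pp50)$n, 1021)
  expect_equal(discretizeChromosome(1500, pp50)$n, 1)   # single-bead limit
  expect_equal(discretizeChromosome(1501, pp50)$n, 2)
  expect_error(discretizeChromosome(-5, pp50), "positive")
})

test_that("rDNA interval is replaced by the configured enlarged beads", {
  geom <- nucleusGeometry()  # 150 beads, V = 14%
  d <- discretizeChromosome(1078177, pp50, rdnaInterval = c(451000, 468900),
                            centromereBp = 150828, geometry = geom)
  expect_equal(sum(d$isRdna), 150)
  expect_equal(unique(d$diam[d$isRdna]), geom@rdnaDiameter)
  expect_equal(d$n, ceiling((1078177 - 17900) / 1500) + 150)
  expect_error(discretizeChromosome(1000, pp50, rdnaInterval = c(900, 1200),
                                    geometry = geom),
               "outside")
})

test_that("rDNA diameter reproduces the published volume-fraction values", {
  # 150 beads in a 1000 nm nucleus
  expect_true(abs(rdnaDiameterFromVolumeFraction(0.14, 1000, 150) - 195) < 1.5)
  expect_true(abs(rdnaDiameterFromVolumeFraction(0.05, 1000, 150) - 138.6) < 1)
  expect_true(abs(rdnaDiameterFromVolumeFraction(0.30, 1000, 150) - 251.5) < 1)
  expect_error(rdnaDiameterFromVolumeFraction(1.2, 1000, 150), "V must")
  # net volume identity: n (pi/6) d^3 / ((4/3) pi R^3) == V
  for (V in c(0.05, 0.14, 0.3)) {
    d <- rdnaDiameterFromVolumeFraction(V, 800, 37)
    Vback <- 37 * (pi / 6) * d^3 / ((4 / 3) * pi * 800^3)
    expect_equal(Vback, V, tolerance = 1e-9)
  }
})

test_that("total bead count scales as 1 / (C*W) up to ceiling effects", {
  g <- yeastGenome()
  geom <- nucleusGeometry()
  n1 <- nBeads(discretizeGenome(g, parameterPoint(69, 50, 30, 400), geom))
  n2 <- nBeads(discretizeGenome(g, parameterPoint(69, 100, 30, 400), geom))
  nr <- 150
  expect_equal((n2 - nr) / (n1 - nr), 0.5, tolerance = 0.01)
})

test_that("locus-to-bead mapping is deterministic and round-trips", {
  g <- yeastGenome()
  chains <- discretizeGenome(g, pp50, nucleusGeometry())
  # tile oracle: floor((pos - 1) / 1500) + 1
  expect_equal(locusToBead(chains, "chr1", 150000)$bead, 100)
  expect_equal(locusToBead(chains, "chr4", 1)$bead, 1)  # left telomere bead
  cen <- locusToBead(chains, "chr4", g@chromosomes$centromere_bp[4])
  ci <- match("chr4", chains@chainNames)
  expect_equal(cen$globalBead, chains@centromereBead[ci])
  expect_error(locusToBead(chains, "chrX", 100), "unknown chromosome")
  expect_error(locusToBead(chains, "chr1", 9e6), "outside")
  # round-trip: a bead's tile midpoint maps back to the same bead
  for (b in c(1, 50, 100, 153)) {
    gi <- which(chains@beadChain == 1)[b]
    mid <- floor((chains@beadStartBp[gi] + chains@beadEndBp[gi]) / 2) + 1
    expect_equal(locusToBead(chains, "chr1", mid)$bead, b)
  }
  # rDNA chromosome: position inside the interval maps to an rDNA bead
  hit <- locusToBead(chains, "chr12", 460000)
  expect_true(hit$globalBead %in% chains@rdnaBeads)
})

test_that("chain annotations export centromere/telomere/rDNA roles", {
  chains <- discretizeGenome(tinyGenome(), parameterPoint(40, 50, 30, 130),
                             tinyGeometry())
  gr <- chainAnnotations(chains)
  expect_s4_class(gr, "GRanges")
  expect_equal(sum(gr$role == "centromere"), 2)
  expect_equal(sum(gr$role == "telomere"), 4)
  expect_equal(sum(gr$role == "rdna"), 3)
  path <- tempfile(fileext = ".bed")
  writeChainAnnotations(chains, path)
  bed <- read.delim(path, header = FALSE)
  expect_equal(nrow(bed), length(gr))
})
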