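# Shared fixtures: the worked three-allele systems and the two-allele
# illustration of DAA fitness (5 + 4 recognized sites of 10, two sites
# uncovered by the union, so f_AB = 0.8 and pairwise overlap 0.1).

eq12_matrix <- function() {
  fitness_matrix(rbind(c(0.8, 0.9, 0.9),
                       c(0.9, 0.7, 0.8),
                       c(0.9, 0.8, 0.1)), model = "daa")
}

eq13_matrix <- function() {
  fitness_matrix(rbind(c(0.8, 0.8, 0.8),
                       c(0.8, 0.7, 0.7),
                       c(0.8, 0.7, 0.1)), model = "daa")
}

# the printed three-allele recognition layout behind eq12_matrix()
layout_stable_alleles <- function() {
  pats <- rbind(A1 = c(0,1,1,1,1,1,1,1,1,0),
                A2 = c(1,1,1,1,1,1,1,0,0,0),
                A3 = c(0,0,0,0,0,0,0,0,0,1)) > 0
  allele_set(patterns = pats)
}

# two alleles over 10 sites: A recognizes {1,2,3,4,6}, B {6,7,9,10};
# sites 5 and 8 are covered by neither, the intersection is {6}
fig1_alleles <- function() {
  pats <- rbind(A = c(1,1,1,1,0,1,0,0,0,0),
                B = c(0,0,0,0,0,1,1,0,1,1)) > 0
  allele_set(patterns = pats)
}

random_merits <- function(k, lo = 0.05, hi = 0.95) {
  sort(stats::runif(k, lo, hi), decreasing = TRUE)
}
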