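# Shared fixture builders; everything is generated in code.

# Tiny 5-sample OTU table with known singleton/doubleton structure.
toyOtuTable <- function() {
    counts <- rbind(
        OTU_A = c(4000L, 4100L, 3900L, 4200L, 4050L),
        OTU_B = c(3000L, 2900L, 3100L, 2800L, 3000L),
        OTU_C = c(2500L, 2000L, 2200L, 2100L, 2400L),
        OTU_D = c(1L, 0L, 0L, 0L, 0L),      # singleton
        OTU_E = c(1L, 1L, 0L, 0L, 0L),      # doubleton
        OTU_F = c(2L, 1L, 0L, 0L, 0L))      # total 3: retained
    colnames(counts) <- paste0("S", 1:5)
    design <- data.frame(sample_id = paste0("S", 1:5),
                         treatment = c("control", "Ag+", "Ag+", "Ag+", "Ag+"),
                         dose = c(0.1, 1, 10, 50, 93))
    OtuExperiment(counts, design)
}

# Noise-free log-logistic series over a 14-level geometric dose grid.
llSeries <- function(b = 1.5, c = 5, d = 120, e = 8, from = 0.1, to = 500) {
    x <- geomSeq(from, to, 14)
    list(doses = x, responses = evalLogLogistic(c(b = b, c = c, d = d,
                                                  e = e), x))
}

# Bisection oracle for the dose where a response curve crosses `target`,
# independent of the closed forms under test.
bisectRoot <- function(fun, target, lower, upper, iter = 200) {
    g <- function(x) fun(x) - target
    stopifnot(g(lower) > 0, g(upper) < 0)
    for (i in seq_len(iter)) {
        mid <- (lower + upper) / 2
        if (g(mid) > 0) lower <- mid else upper <- mid
    }
    (lower + upper) / 2
}

# Direct Burr III sampler via inverse-CDF (oracle side).
rBurr3 <- function(n, b, c, k) b / (runif(n)^(-1 / k) - 1)^(1 / c)
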