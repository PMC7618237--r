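#!/usr/bin/env Rscript
# Period changes and cross-country statistics: endpoint changes for
# 2001-10 and 2010-19, the seven-category decadal classification,
# regional summaries, population coverage of decline, within-region SDs
# (convergence), the level-change correlation, and regional benchmark
# selection for 2010-19.

suppressPackageStartupMessages({
  library(optparse)
  library(ncdbench)
})
opt <- parse_args(OptionParser(option_list = list(
  make_option("--seed", type = "integer", default = 1L),
  make_option("--out", type = "character", default = "results")
)))

probs <- utils::read.csv(file.path(opt$out, "probabilities", "probabilities.csv"))
rmap <- read_region_map(file.path(opt$out, "synthetic", "region_map.csv"))

ch1 <- change_table(probs, 2001, 2010)
ch2 <- change_table(probs, 2010, 2019)
m <- merge(ch1[, c("country", "sex", "delta")],
           ch2[, c("country", "sex", "delta")],
           by = c("country", "sex"), suffixes = c("_2001_2010", "_2010_2019"))
cls <- classify_decadal(m$delta_2001_2010, m$delta_2010_2019)
classifications <- data.frame(m, category = cls$category,
                              direction = cls$direction)

summaries <- list()
benchmarks <- list()
for (sx in c("female", "male")) {
  chs <- ch2[ch2$sex == sx, ]
  rs <- region_summary(chs, rmap)
  rs$sex <- sx
  summaries[[sx]] <- rs
  lv <- probs[probs$year == 2010 & probs$sex == sx, c("country", "value")]
  bm <- select_benchmark(chs, rmap, eligible = high_quality_countries(rmap),
                         levels = lv)
  if (nrow(bm)) bm$sex <- sx
  benchmarks[[sx]] <- bm

  cat(sprintf(
    "%s: %d of %d countries declining 2010-19 (%.0f%% of population); r(level, change) = %.2f\n",
    sx, sum(chs$delta < 0), nrow(chs),
    100 * population_coverage(chs, rmap, sx),
    level_change_correlation(chs, lv)))
}

conv <- do.call(rbind, lapply(c(2010, 2019), function(yr) {
  do.call(rbind, lapply(c("female", "male"), function(sx) {
    v <- probs[probs$year == yr & probs$sex == sx, c("country", "value")]
    cs <- convergence_sd(data.frame(country = v$country, value = 100 * v$value),
                         rmap)
    cs$year <- yr; cs$sex <- sx
    cs
  }))
}))

write_results(
  list(changes = rbind(ch1, ch2),
       classifications = classifications,
       region_summary = do.call(rbind, summaries),
       convergence_sd = conv,
       benchmarks = do.call(rbind, benchmarks)),
  file.path(opt$out, "trends"), seed = opt$seed)

tab <- table(classifications$direction, classifications$sex)
cat("Decadal direction counts (countries):\n")
print(tab)
cat("Benchmarks:\n")
print(do.call(rbind, benchmarks))
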