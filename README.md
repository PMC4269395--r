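# trialnet

Clinical research is increasingly carried out across borders: a single
registered study may run sites in many countries at once, and the set of
studies two countries have shared is a direct, data-driven measure of how
tightly their research systems are linked. **trialnet** turns clinical
trial registry records into a weighted country co-participation network
and computes the statistics used to describe the globalization of clinical
research. It is aimed at meta-researchers, health-policy analysts, and
anyone auditing registry dumps (e.g. ClinicalTrials.gov bulk downloads).

## The model

Each *multinational* study — one conducted in $k > 1$ distinct countries —
contributes all $\binom{k}{2}$ unordered country pairs to a master list of
connection instances. Collapsing the master list gives an undirected
weighted network: the weight of edge $\{a,b\}$,

$$w_{ab} = \#\{\text{studies in which both } a \text{ and } b \text{ participated}\},$$

is the pair's multiplicity, and a country's node size is its weighted
degree $s_a = \sum_b w_{ab}$, satisfying
$\sum_a s_a = 2 \sum_{a<b} w_{ab}$. On top of the network the package
computes total connections, per-country and per-region totals and shares
(with an explicit edge-to-region attribution policy), the cross-region
share, the strongest edges, regional study-participation proportions,
per-year study counts with year-over-year and annualized growth, and
top-k condition tables per region. A seeded synthetic registry generator
with analytic expected edge weights makes the whole pipeline testable
offline.

## Worked example

Study A runs in countries 1, 2, 3; study B in countries 2, 3, 4.

```r
library(trialnet)
reg <- trial_registry(c("A", "B"), c(2000L, 2001L),
                      countries = list(c("1", "2", "3"), c("2", "3", "4")))
net <- build_network(reg)
net
#> <trial_network> 4 countries, 5 edges, total weight 6 (from 2 multinational studies)
net$edges
#>   u v weight
#> 1 1 2      1
#> 2 1 3      1
#> 3 2 3      2
#> 4 2 4      1
#> 5 3 4      1
```

Every pair shares one study except countries 2 and 3, which shared both —
weight 2. Node sizes are weighted degrees, and shares are fractions of the
endpoint-incidence mass $2W = 12$:

```r
country_connection_totals(net)
#>   country total     share
#> 1       2     4 0.3333333
#> 2       3     4 0.3333333
#> 3       1     2 0.1666667
#> 4       4     2 0.1666667

rmap <- c("1" = "Europe", "2" = "Europe", "3" = "Asia", "4" = "Asia")
cross_region_share(net, rmap)
#> [1] 0.6666667
region_connection_totals(net, rmap)   # endpoint_half: shares sum to 1
#>   region mass share
#> 1   Asia    3   0.5
#> 2 Europe    3   0.5
```

4 of the 6 connection instances join a Europe-mapped country with an
Asia-mapped one, hence the cross-region share of 2/3.

A synthetic registry exercises the full pipeline at scale:

```r
sim <- generate_registry(registry_config(5000), seed = 42)
mult <- filter_multinational(sim$registry)
bignet <- build_network(mult)
bignet
#> <trial_network> 30 countries, 435 edges, total weight 16302 (from 546 multinational studies)
top_edges(bignet, 3)
#>        u             v weight
#> 1 Canada United States    237
#> 2 Mexico United States    191
#> 3 Canada        Mexico    180
ser <- studies_per_year(mult, quiet = TRUE)
peak_year(ser)
#> $year
#> [1] 2009
#> $n_studies
#> [1] 78
annualized_growth(ser, 1990, 2009)$value   # mean year-over-year growth
#> [1] 0.6030985
```

The hub country dominates the strongest edges, the planted 2009 peak is
recovered, and the mean year-over-year growth over 1990–2009 reflects the
configured exponential rise. `build_network(mult)$edges` matches
`sim$ground_truth$pair_counts` exactly.

## Command line

```sh
Rscript inst/cli/trialnet simulate --n 5000 --seed 42 --out sim/
Rscript inst/cli/trialnet run --input sim/registry.tsv --out results/
```

Subcommands `run`, `ingest`, `build-network`, `metrics`, `trends`,
`conditions`, `simulate`; outputs include a sorted edge list (CSV),
GraphML and GEXF exports loadable in Gephi, CSV/JSON summary tables, and a
run log with record counts at every filter stage.

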