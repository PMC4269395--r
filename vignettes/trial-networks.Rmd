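---
title: "Methods: country co-participation networks from trial registries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: country co-participation networks from trial registries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A clinical trial registry records, for each registered study, the set of
countries where it is carried out. A study is *multinational* when that set
has more than one element; only multinational studies carry information
about connections between countries, and only they enter the network.

A multinational study conducted in $k$ countries contributes all
$\binom{k}{2}$ unordered country pairs as *connection instances*. Pooling
the instances of every study gives the *master list*, a multiset of pairs.
The network collapses the multiset: countries are nodes, each distinct pair
$\{a,b\}$ is an undirected edge whose weight

$$w_{ab} = \#\{\text{studies in which both } a \text{ and } b
\text{ participated}\}$$

equals the pair's multiplicity in the master list. A country's *node size*
is its weighted degree $s_a = \sum_b w_{ab}$, and the degree-sum identity
$\sum_a s_a = 2\sum_{a<b} w_{ab}$ holds by construction. Countries are
weighted equally regardless of how many sites or participants they host;
site-level and enrollment-level weighting are deliberately out of scope.

```{r}
library(trialnet)
reg <- trial_registry(c("A", "B"), c(2000L, 2001L),
                      countries = list(c("1", "2", "3"), c("2", "3", "4")))
build_network(reg)$edges
```

Two three-country studies sharing countries 2 and 3 yield five edges, all
of weight 1 except the 2–3 edge with weight 2 — the canonical worked
example that `scripts/acceptance.R` recomputes.

## Summary statistics

*Total connections* is the sum of edge weights (equivalently, the
master-list size). *Country totals* are weighted degrees; a country's
share is $s_a / 2W$ with $W$ the total weight, so shares sum to 1.

**Region attribution.** Each country belongs to exactly one of six regions
(North America, South America, Africa, Europe, Asia, Oceania). An edge may
span two regions, and published regional percentages that sum to 100%
require an attribution rule that is rarely stated. We default to
`endpoint_half`: an edge gives half its weight to each endpoint's region.
It is the unique symmetric rule whose region shares sum to 1 while keeping
an intra-region edge's full weight in its region. `endpoint_full` (each
endpoint's region receives the full weight; shares computed over $2W$) is
available when region masses should read as incidence counts; the two
differ by an exact factor of 2 in mass and agree in share ordering. The
*cross-region share* — the fraction of total weight on edges whose
endpoints lie in different regions — is policy-free.

Region membership of transcontinental countries is a modelling choice, not
a fact: the shipped map places Russia in Europe, Turkey and Georgia in
Asia, Egypt in Africa, and Mexico with Central America and the Caribbean
in North America. Every assignment is overridable via a plain TSV passed
to `read_region_map()`.

**Participation.** Separately from edge weights, a region *participates*
in a study when at least one of its countries is listed. One study can
touch several regions, so participation proportions may sum to more than
one; this is documented output, not an error. Weighted degree,
distinct-neighbour count, and study-participation count answer different
questions and are deliberately exposed as distinct metrics
(`country_connection_totals()`, the edge table, and
`participation_report()`), because published per-country "connection"
figures often mix them and cannot be reconciled under any single
definition.

## Trends

Studies are binned by start year on a contiguous axis (gap years
zero-filled). Year-over-year growth is $g_t = (n_t - n_{t-1})/n_{t-1}$,
undefined — flagged `NA`, never coerced to zero — when $n_{t-1}=0$.
For a window $(y_0, y_1]$, the default annualized growth is the arithmetic
mean of the defined $g_t$; the compound rate
$(n_{y_1}/n_{y_0})^{1/(y_1-y_0)}-1$ is the `cagr` alternative. The
arithmetic mean is the default because registry series begin with years of
tiny counts whose explosive early ratios dominate; a large mean-growth
figure over such a window is arithmetically impossible to reproduce as a
CAGR ending at a few-thousand-study peak, so the mean is the only reading
consistent with how such figures are reported. Peak detection takes the
earliest year on ties.

## Conditions by region

Condition labels are free text; we case-fold and trim at ingestion and
support an optional user synonym map (e.g. `"diabetes mellitus, type 2"`
→ `"diabetes"`). No ontology (MeSH) rollup is attempted, so two spellings
not covered by the synonym map count separately — condition tables are
therefore comparable within a run, not across vocabularies. A study counts
toward every region it touches and every condition it lists; the
proportion denominator is the number of multinational studies touching the
region. Ties at the cutoff rank are reported jointly rather than broken
arbitrarily.

## The synthetic registry generator

`generate_registry()` draws a registry with the structure the analysis
assumes, so every stage is testable offline:

| parameter | default | what it encodes |
|---|---|---|
| `p_multinational` | 0.11 | ~89/11 single-nation/multinational split of real registries |
| `mean_countries` | 6.5 | multinational studies average 6–7 countries; country count is 2 + geometric, truncated at the universe size with the success probability solved numerically so the *truncated* mean hits the target |
| universe | 30 countries over the six regions | small enough for exact oracles, rich enough to exercise every metric |
| popularity | rank$^{-0.8}$ with one hub at 10× the median | heavy-tailed country participation with one dominant country |
| `year_profile` | exp. rise (25%/yr) to a 2009 peak, then 8%/yr decline | growth-then-plateau temporal shape |
| `condition_probs` | diabetes-led categorical (28% diabetes) | a few conditions dominate |
| `p_unlocated`, `p_missing_year` | 0.01, 0.02 | dirty registry rows |

Countries are sampled without replacement with probability proportional to
popularity by successive renormalization (base R `sample()` semantics).
The generator records ground truth — realized scope labels, per-pair
co-occurrence counts accumulated independently of the network builder,
and per-year counts — so pipeline recovery is checked *exactly*, not in
expectation.

**Analytic expected edge weights.** For the recovery tests we need
$\mathbb{E}[w_{ab}]$ under the sampling scheme. Sequential weighted
sampling without replacement is equivalent to ranking independent
exponentials $E_i \sim \mathrm{Exp}(w_i)$ and taking the $k$ smallest, so

$$P(a, b \text{ both drawn} \mid k) = \int_0^\infty
f_{\max(E_a,E_b)}(x)\; P\!\left(N_{\text{others}}(x) \le k-2\right) dx,$$

where $N_{\text{others}}(x)$ counts the other countries with $E_i < x$ —
a Poisson-binomial variable whose CDF is computed by dynamic program — and
the integral is evaluated by adaptive quadrature. This is exact (no
Monte-Carlo fallback is needed at the default universe size); a
Monte-Carlo estimator is retained as an independent cross-check and agrees
within sampling error in the test suite.

**What a green test does and does not establish.** The generator emulates
marginal structure: the scope split, study sizes, a popularity hierarchy,
a unimodal year profile, condition skew. It does not reproduce real
registries' country-popularity correlations (e.g. regulatory blocs
entering studies together), duplicate-record patterns beyond simple id
repetition, or real condition vocabulary. Green tests establish that the
pipeline computes the declared statistics correctly, not that any
particular real-world figure is right.

## Numerical and degenerate-input choices

- Edge identity is canonical: pairs stored with $u < v$ lexicographically;
  all writers sort, so repeated runs are byte-identical.
- Edge weights are exact integers; nothing is normalized at build time.
- Rankings break ties lexicographically (countries, conditions, pairs).
- Empty network: total is 0; country totals are an empty table;
  cross-region share is an *error* (0/0), not 0.
- Studies with no parseable country list are kept at ingestion, labelled
  `unlocated`, and excluded from every analysis; studies with an
  unparseable start date are excluded from trend analyses only, and still
  contribute edges.
- Duplicate records merge by union of countries and conditions with the
  earliest non-missing year (registry updates append locations);
  conflicting years warn.
- Start years outside a 1900–2100 plausibility window become missing.
- Lenient mode (default) warns and continues on unknown countries and
  unmapped regions (an `"Unassigned"` bucket); strict mode makes both
  fatal, and the pipeline tags every error with its stage.

## Known limitations

- Real published counts at full-registry scale are not asserted anywhere:
  the public figures reported alongside this kind of analysis contain
  internal inconsistencies (single-nation and multinational counts that do
  not sum to the stated total of unique studies; a global connection count
  reproducible under no identifiable counting rule — it is close to
  $\sum_s (k_s - 1)$ but that rule is nowhere defined; an abstract
  multinational count that differs from the methods'). The pipeline
  instead logs its stage counts (records read, unique studies, scope
  split, dated multinational studies) so a real snapshot can be audited
  line by line against any published figure.
- Visual layout is out of scope; the GEXF/GraphML exports are intended for
  Gephi.
- No statistical inference (null models, significance) is performed on the
  network.
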