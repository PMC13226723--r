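# wgscost

Bottom-up (micro-)costing of clinical whole-genome plus whole-transcriptome
sequencing (WGS/WTS) of tumour/normal pairs.

Comprehensive genomic profiling by WGS/WTS is the most complete molecular
diagnostic for solid tumours, but its per-case cost decides whether a
diagnostic centre can offer it routinely. `wgscost` is for laboratory
directors, health economists and molecular pathology groups who need to
answer questions like: *what does one case actually cost at our volume, what
happens at 500x coverage, when do we need a second sequencer, and what does
inflation do to the budget over a decade?*

The package separates the **itemised inputs** (a cost ledger: consumables,
personnel roles, equipment, data-processing costs, an R&D flat fee) from the
**allocation rules** that turn them into a per-case cost breakdown across
seven categories: WGS consumables, WTS consumables, personnel, equipment
capital, equipment maintenance, research & development, and computational
data analysis/storage.

## The model in brief

**Throughput.** Coverage, flow-cell output and laboratory efficiency are
linked by

d_T + d_N = ½ · e · n_reads · n_cycles / (n_patients · n_genome)

where d_T and d_N are tumour and normal mean coverage, the factor ½ accounts
for paired-end sequencing, e is the lab-specific sequencing efficiency
(0.44 for an FFPE workflow; 1 would be ideal), n_reads and n_cycles describe
the flow cell and n_genome = 3.3×10⁹ bases. Solving for n_patients and
flooring gives patients per flow cell; list price divided by that number
gives the flow-cell cost per case. At the defaults (100x/30x, 25B flow
cell) eight patients share one flow cell.

**Allocation.** Consumables and data costs are volume-independent per case;
equipment capital is amortised over its operating life (7 years; 5 for the
sequencer and compute server) and divided by annual volume, as are
maintenance, annual-FTE personnel and the R&D fee. The *idealised* scenario
costs hands-on roles by minutes × wage-per-minute; the *realistic* scenario
staffs whole or half positions with vacation/sick-leave redundancy, adds
backup equipment, and applies a re-sequencing error surcharge (default 1%)
to consumables and compute costs.

**Capacity.** One platform sequences 2500 cases/year at 100x tumour
coverage; capacity scales inversely with tumour coverage, and fleet size is
the ceiling of volume over capacity — the source of the cost jump at each
capacity boundary in volume sweeps.

## Worked example

```r
library(wgscost)

ledger <- calibrated_ledger("twist")       # shipped synthetic ledger
b <- total_cost_per_case(ledger, caseload_scenario(300))
b
#> <cost_breakdown> idealised, 300 cases/year, error 0%, overhead 0%
#>   consumables_wgs           2190.92
#>   consumables_wts            278.86
#>   personnel                  747.59
#>   equipment_capital         1056.67
#>   equipment_maintenance      428.90
#>   research_development       138.11
#>   data_analysis_storage      432.06
#>   total per case            5273.11
```

Per case at 300 cases/year, consumables dominate (2469.78 EUR, ~47% of the
total, 2060.00 EUR of which is the flow cell); personnel costed by hands-on
minutes come to 747.59 EUR. The same ledger at 2000 cases/year totals
3455.00 EUR — only the 1/volume categories shrink. The realistic scenario
(position staffing, backup equipment, 1% re-sequencing) raises the 300-case
figure to 7611.35 EUR:

```r
round_cents(breakdown_total(
  total_cost_per_case(ledger, caseload_scenario(300, "realistic"))))
#> [1] 7611.35

flowcell_table(flowcell_catalogue(), sequencing_config())
# per-case flow-cell costs from 2060 (NovaSeq X 25B) to 65,500 EUR
# (benchtop mid-output cell, where 50 whole flow cells are needed per case)

sw <- volume_sweep(ledger)                  # 100-4000 cases/year
autoplot(sw)                                # capacity step at 2500 cases
```

Sweeps (`volume_sweep()`, `coverage_sweep()`), deterministic
inflation/deflation projection (`project_economics()`) and protocol
comparison (`compare_protocols()`) all return tibbles that pipe straight
into dplyr/ggplot2; `tidy()` and `glance()` methods are provided. A thin
command-line front end lives at `inst/cli/wgscost.R`.

The shipped ledger is *synthetic but calibrated*: only aggregate figures of
the underlying cost study are public, and the per-item lines are back-solved
so that every published aggregate is reproduced to the cent (see the methods
vignette, `vignettes/costing-model.Rmd`).

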