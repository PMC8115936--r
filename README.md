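# hiveESF

Honeybee bodies charge electrostatically by friction — between body parts,
between bees in the crowded hive, and against the air in flight. When a bee
performs one of the colony's stereotyped social behaviors, its moving body
modulates the surrounding electrostatic field (ESF) in a characteristic
way, and capacitive sensors mounted inside a hive can pick these patterns
up continuously without disturbing the colony. hiveESF is the desk-side
toolkit for such a monitoring rig: it defines the recording containers,
simulates ground-truth signal streams, and detects, classifies and decodes
the social signals in six-channel ESF recordings. It is written for
researchers and beekeeping projects that run in-hive ESF loggers and need
a reproducible, scriptable analysis path.

## The signals and the rules

Three signal classes are distinguished by frequency band and time course:

| class | behavior | band | duration rule |
|-------|----------|------|----------------|
| WRS | waggle-dance run | 5–25 Hz abdomen (WRS_L) + 190–230 Hz wing (WRS_H), partially synchronized | ~0.4–10 s |
| SRS | short pulses (begging/stop contexts) | > 350 Hz fundamental + harmonics | < 1 s |
| FRS | wing fanning (ventilation) | 90–120 Hz, highly regular | > 15 s |

The detector computes Hann-window STFT band-power traces at two
resolutions (1 s windows for the low band, 0.2 s for the high bands),
segments each trace where power exceeds `k = 4` times a rolling-median
baseline (hysteresis 0.5), refines interval edges to the half-power
crossing, and applies the class rules in the priority order FRS > SRS >
WRS. For an accepted waggle run the abdomen band is band-passed
(zero-phase) and the waggle cycles *n* are counted from zero crossings;
the advertised foraging distance follows the classic dance calibration

```
distance = n × 75 m
```

Runs repeated in quick succession (gaps < 5 s) are grouped into dance
bouts whose median cycle count gives a stabilized distance estimate.
Entrance traffic is counted from the 100 S/s two-ring capacitance stream,
and 120 s-cadence telemetry (hive/ambient temperature, humidity, load
cells) supports environment correlation reports (Spearman rank
correlation, Welch seasonal comparisons).

## Worked example

Simulate a minute of hive recording with two waggle runs, one fanning
episode and one short pulse, all at 10 dB band-local SNR in realistic hive
noise (pink + white + 50 Hz mains + low-frequency crowd clutter), then
detect:

```r
library(hiveESF)
sc <- scenario(
  duration = 60,
  events = list(
    scenarioEvent("WRS", 1, 5,  waggleRunSpec(nWaggles = 12), snrDb = 10),
    scenarioEvent("WRS", 1, 8,  waggleRunSpec(nWaggles = 13), snrDb = 10),
    scenarioEvent("FRS", 2, 10, fanningSpec(105, 18, 0.02),   snrDb = 10),
    scenarioEvent("SRS", 3, 20, srsSpec(420, 0.4),            snrDb = 10)),
  noise = noiseSpec(), seed = 42)
out <- renderScenario(sc)
events <- detectSignals(out$recording)
print(events, digits = 4)
#>   label channel t_start  t_end n_waggles distance_m mean_power regularity
#> 1   WRS       1   5.022  5.956        13        975    12220.1         NA
#> 2   WRS       1   7.922  9.046        14       1050    20805.7         NA
#> 3   FRS       2  10.017 27.970        NA         NA     1667.5     0.9085
#> 4   SRS       3  20.087 20.314        NA         NA      403.3         NA
```

All four events are recovered at their simulated spans; the waggle counts
sit within one cycle of the simulated truth (12 and 13), so the decoded
distances are within 75 m of the true values. The fanning event's
regularity index (0.91) documents why it passed the "highly regular"
rule. Grouping and scoring:

```r
groupBouts(events)
#>   channel t_start t_end n_runs total_waggles median_waggles distance_m
#> 1       1   5.022 9.046      2            27           13.5       1012
evaluateEvents(events, out$truth)$perClass[, c("label", "precision", "recall")]
#>   label precision recall
#> 1   FRS         1      1
#> 2   SRS         1      1
#> 3   WRS         1      1
```

`writeESFBinary()` / `readESFBinary()` store recordings in the package's
24-bit binary container; `esfToCSV()` converts to 200 s CSV chunks;
`esfToWAV()` exports a channel for listening in audio software. A thin
command-line front end over the same functions lives at
`inst/scripts/hiveesf` (subcommands `simulate`, `convert`, `detect`,
`evaluate`, `report`).

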