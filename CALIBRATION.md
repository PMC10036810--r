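# Provenance of the shipped model configuration

The default parameter set in `R/default-config.R` (and its YAML copy,
`inst/extdata/rabbit_default.yaml`) was produced by a one-off calibration
and then frozen; nothing in the package re-fits parameters at run time.

## Targets

The calibration targets are the headline electrophysiological quantities of
the isolated rabbit AV node, as established in the experimental literature
and reproduced by compact nodal models:

* free-running sinus cycle length 361 ms (166 bpm);
* sinus-beat conduction latencies SN→AM3 = 43.7 ms, SN→PB = 92.4 ms,
  SN→HB6 = 139.6 ms;
* subsidiary (slow-pathway) escape rhythm of 600 ms with a silent SN;
* anterograde nodal effective refractory period (ERPN) 94 ms, unchanged by
  fast-pathway ablation, prolonged to 132 ms by slow-pathway ablation;
* retrograde ERPN 163 ms, unchanged by either ablation;
* anterograde functional refractory period (FRPN) 180.5 ms;
* perpetual slow–fast reentry for coupling intervals of roughly 95–122 ms;
* 5:4 Wenckebach conduction at a 125.2 ms atrial pacing interval
  (His rate 384 bpm);
* mean His–His interval ≈ 177 ms under random uniform 75–125 ms atrial
  pacing (≈ 205 ms after SP ablation; mean rate ≈ 318 bpm after FP
  ablation);
* uncoupled refractory-period bands: atrium 68 ± 11 ms, inferior nodal
  extension 91 ± 10 ms, transitional zone 141 ± 15 ms, sinus node
  166 ± 30 ms.

## Procedure

1. **Single-cell maps.** Uncoupled refractory period and action-potential
   duration were mapped against `(eps0, mu1, a, ct)` for excitable cells,
   and intrinsic period against `(a1, ct, mu1, eps0)` for pacemaking cells,
   using the package's own engine.
2. **Structural design.** Conduction-delay-versus-`d` curves fixed the
   coupling profile; the asymmetry region and magnitudes were chosen so
   retrograde conduction is realistically slow, a reverse circus rhythm is
   impossible, and the correct slow–fast reentry survives. Pacemaker
   placement (active SN and SP8; latent SP7/SP9/SP10/FP8/PB) follows a
   growth-versus-load stability analysis described in the methods vignette.
3. **Coordinate descent.** Cell-group refractoriness (`eps0`, `mu1`,
   thresholds), the coupling and asymmetry profiles, and the latent-cell
   current magnitudes were optimized by coordinate descent against the
   deterministic targets above (sweep-level quantities evaluated on coarse
   S2 grids), with hard gates rejecting any candidate whose sinus beat,
   escape rhythm, capture behaviour or baseline pathway order was wrong.
4. **Rate pinning.** With everything else frozen, `a1` of SN and SP8 were
   tuned last by bisection so the coupled model free-runs at 361 ms and
   escapes at 600 ms, and the atrial/FP/HB coupling was rescaled for the
   exact latencies.

The calibrated values live only in `R/default-config.R`; the YAML file is
generated from it and verified equal by a test.
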