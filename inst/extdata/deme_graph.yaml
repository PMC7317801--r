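demes:
- Europe
- MiddleEast
- CentralNorthEurasia
- EastEurasia
- Beringia
- ArcticNorthAmerica
- NorthAmerica
edges:
- - Europe
  - MiddleEast
- - Europe
  - CentralNorthEurasia
- - MiddleEast
  - CentralNorthEurasia
- - CentralNorthEurasia
  - EastEurasia
- - CentralNorthEurasia
  - Beringia
- - EastEurasia
  - Beringia
- - Beringia
  - NorthAmerica
- - Beringia
  - ArcticNorthAmerica
- - NorthAmerica
  - ArcticNorthAmerica
stat_groups:
  Europe: EUR
  MiddleEast: ME
  CentralNorthEurasia: EAS
  EastEurasia: EAS
  Beringia: EAS
  ArcticNorthAmerica: AME
  NorthAmerica: AME
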