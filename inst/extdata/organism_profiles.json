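{
  "Chlamydomonas": {
    "ASO": true, "QS": true, "QPT": true, "NMNAT": true, "NS": true,
    "TDO": false, "IDO": true, "AFMID": false, "KMO": true,
    "KYNU": false, "3HAO": false,
    "NAMase": true, "NAPRT": false, "NAMPT": true, "SIRT": true
  },
  "Volvox": {
    "ASO": true, "QS": true, "QPT": true, "NMNAT": true, "NS": true,
    "TDO": false, "IDO": false, "AFMID": false, "KMO": false,
    "KYNU": false, "3HAO": false,
    "NAMase": false, "NAPRT": false, "NAMPT": true, "SIRT": true
  },
  "Ostreococcus_lucimarinus": {
    "ASO": true, "QS": true, "QPT": true, "NMNAT": true, "NS": true,
    "TDO": false, "IDO": false, "AFMID": false, "KMO": false,
    "KYNU": false, "3HAO": false,
    "NAMase": true, "NAPRT": true, "NAMPT": false, "SIRT": true
  },
  "Ostreococcus_tauri": {
    "ASO": true, "QS": true, "QPT": true, "NMNAT": true, "NS": true,
    "TDO": false, "IDO": false, "AFMID": false, "KMO": false,
    "KYNU": false, "3HAO": false,
    "NAMase": true, "NAPRT": true, "NAMPT": false, "SIRT": true
  },
  "Monosiga": {
    "ASO": false, "QS": false, "QPT": true, "NMNAT": true, "NS": true,
    "TDO": true, "IDO": true, "AFMID": true, "KMO": true,
    "KYNU": true, "3HAO": true,
    "NAMase": false, "NAPRT": false, "NAMPT": true, "SIRT": true
  },
  "Arabidopsis": {
    "ASO": true, "QS": true, "QPT": true, "NMNAT": true, "NS": true,
    "TDO": false, "IDO": false, "AFMID": false, "KMO": false,
    "KYNU": false, "3HAO": false,
    "NAMase": true, "NAPRT": true, "NAMPT": false, "SIRT": true
  },
  "human": {
    "ASO": false, "QS": false, "QPT": true, "NMNAT": true, "NS": true,
    "TDO": true, "IDO": true, "AFMID": true, "KMO": true,
    "KYNU": true, "3HAO": true,
    "NAMase": false, "NAPRT": true, "NAMPT": true, "SIRT": true
  }
}
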