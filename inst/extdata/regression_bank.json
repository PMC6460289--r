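{
  "net_weak_inhibition": {
    "R_bar": 0.688079318273238,
    "CV_bar": 0.00452094512447621,
    "F_bar": 10.5449386888078,
    "label": "desynchronized_spikes"
  },
  "net_strong_inhibition": {
    "R_bar": 0.181852643672999,
    "CV_bar": 0.00787041891750747,
    "F_bar": 10.4288758988503,
    "label": "desynchronized_spikes"
  },
  "synth_sync_spikes": {
    "R_bar": 1,
    "CV_bar": 0,
    "F_bar": 10,
    "label": "synchronized_spikes"
  },
  "synth_desync_spikes": {
    "R_bar": 0.0230176168026686,
    "CV_bar": 0,
    "F_bar": 10,
    "label": "desynchronized_spikes"
  },
  "synth_sync_bursts": {
    "R_bar": 1,
    "CV_bar": 1.92583546824023,
    "F_bar": 10.8120035304501,
    "label": "synchronized_bursts"
  },
  "synth_desync_bursts": {
    "R_bar": 0.151079115829965,
    "CV_bar": 1.01068927924841,
    "F_bar": 2.93676887399956,
    "label": "desynchronized_bursts"
  }
}
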