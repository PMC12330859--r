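# Default 40-ROI profile axis: 20 bilateral pairs in left/right-interleaved
# order (left member first). This file fixes and persists the ROI order that
# labels every connectivity-profile column.
rois:
  - {id: 1, name: "Superior temporal gyrus L", hemisphere: L, lobe: temporal, pair: 2}
  - {id: 2, name: "Superior temporal gyrus R", hemisphere: R, lobe: temporal, pair: 1}
  - {id: 3, name: "Middle temporal gyrus L", hemisphere: L, lobe: temporal, pair: 4}
  - {id: 4, name: "Middle temporal gyrus R", hemisphere: R, lobe: temporal, pair: 3}
  - {id: 5, name: "Inferior temporal gyrus L", hemisphere: L, lobe: temporal, pair: 6}
  - {id: 6, name: "Inferior temporal gyrus R", hemisphere: R, lobe: temporal, pair: 5}
  - {id: 7, name: "Anterior temporal lobe L", hemisphere: L, lobe: temporal, pair: 8}
  - {id: 8, name: "Anterior temporal lobe R", hemisphere: R, lobe: temporal, pair: 7}
  - {id: 9, name: "Parietal lobe L", hemisphere: L, lobe: parietal, pair: 10}
  - {id: 10, name: "Parietal lobe R", hemisphere: R, lobe: parietal, pair: 9}
  - {id: 11, name: "Supramarginal gyrus L", hemisphere: L, lobe: parietal, pair: 12}
  - {id: 12, name: "Supramarginal gyrus R", hemisphere: R, lobe: parietal, pair: 11}
  - {id: 13, name: "Angular gyrus L", hemisphere: L, lobe: parietal, pair: 14}
  - {id: 14, name: "Angular gyrus R", hemisphere: R, lobe: parietal, pair: 13}
  - {id: 15, name: "Frontal lobe L", hemisphere: L, lobe: frontal, pair: 16}
  - {id: 16, name: "Frontal lobe R", hemisphere: R, lobe: frontal, pair: 15}
  - {id: 17, name: "Precentral gyrus L", hemisphere: L, lobe: frontal, pair: 18}
  - {id: 18, name: "Precentral gyrus R", hemisphere: R, lobe: frontal, pair: 17}
  - {id: 19, name: "Superior frontal gyrus L", hemisphere: L, lobe: frontal, pair: 20}
  - {id: 20, name: "Superior frontal gyrus R", hemisphere: R, lobe: frontal, pair: 19}
  - {id: 21, name: "Occipital lobe L", hemisphere: L, lobe: occipital, pair: 22}
  - {id: 22, name: "Occipital lobe R", hemisphere: R, lobe: occipital, pair: 21}
  - {id: 23, name: "Lingual gyrus L", hemisphere: L, lobe: occipital, pair: 24}
  - {id: 24, name: "Lingual gyrus R", hemisphere: R, lobe: occipital, pair: 23}
  - {id: 25, name: "Anterior cingulate gyrus L", hemisphere: L, lobe: limbic, pair: 26}
  - {id: 26, name: "Anterior cingulate gyrus R", hemisphere: R, lobe: limbic, pair: 25}
  - {id: 27, name: "Posterior cingulate gyrus L", hemisphere: L, lobe: limbic, pair: 28}
  - {id: 28, name: "Posterior cingulate gyrus R", hemisphere: R, lobe: limbic, pair: 27}
  - {id: 29, name: "Insula L", hemisphere: L, lobe: limbic, pair: 30}
  - {id: 30, name: "Insula R", hemisphere: R, lobe: limbic, pair: 29}
  - {id: 31, name: "Hippocampus L", hemisphere: L, lobe: limbic, pair: 32}
  - {id: 32, name: "Hippocampus R", hemisphere: R, lobe: limbic, pair: 31}
  - {id: 33, name: "Amygdala L", hemisphere: L, lobe: limbic, pair: 34}
  - {id: 34, name: "Amygdala R", hemisphere: R, lobe: limbic, pair: 33}
  - {id: 35, name: "Parahippocampal gyrus L", hemisphere: L, lobe: limbic, pair: 36}
  - {id: 36, name: "Parahippocampal gyrus R", hemisphere: R, lobe: limbic, pair: 35}
  - {id: 37, name: "Caudate nucleus L", hemisphere: L, lobe: none, pair: 38}
  - {id: 38, name: "Caudate nucleus R", hemisphere: R, lobe: none, pair: 37}
  - {id: 39, name: "Cerebellum L", hemisphere: L, lobe: none, pair: 40}
  - {id: 40, name: "Cerebellum R", hemisphere: R, lobe: none, pair: 39}
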