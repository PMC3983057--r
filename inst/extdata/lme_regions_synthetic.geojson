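{
  "type": "FeatureCollection",
  "name": "Synthetic simplified Large Marine Ecosystem regions (qualitative stand-ins, not analysis polygons)",
  "features": [
    {"type": "Feature",
     "properties": {"label": "BS", "name": "Bering Sea Shelf (<= 1000 m, approximate isobath split)"},
     "geometry": {"type": "Polygon", "coordinates": [[
       [-157.0, 55.0], [-166.5, 54.5], [-175.0, 58.0], [-179.9, 61.0],
       [-179.9, 66.0], [-157.0, 66.0], [-157.0, 55.0]]]}},
    {"type": "Feature",
     "properties": {"label": "BB", "name": "Bering Sea Basin (> 1000 m)"},
     "geometry": {"type": "Polygon", "coordinates": [[
       [-166.5, 54.5], [-175.0, 58.0], [-179.9, 61.0], [-179.9, 52.2],
       [-172.0, 52.5], [-166.5, 54.5]]]}},
    {"type": "Feature",
     "properties": {"label": "AS", "name": "Alaska Stream band south of the Aleutian arc"},
     "geometry": {"type": "Polygon", "coordinates": [[
       [-179.9, 52.2], [-172.0, 52.5], [-166.5, 54.3], [-160.0, 54.8],
       [-155.0, 56.5], [-155.0, 54.5], [-160.0, 53.0], [-166.5, 52.3],
       [-172.0, 50.7], [-179.9, 50.2], [-179.9, 52.2]]]}},
    {"type": "Feature",
     "properties": {"label": "NP", "name": "North Pacific Ocean"},
     "geometry": {"type": "Polygon", "coordinates": [[
       [-179.9, 50.2], [-172.0, 50.7], [-166.5, 52.3], [-160.0, 53.0],
       [-155.0, 54.5], [-140.0, 52.0], [-130.0, 50.5], [-130.0, 40.0],
       [-179.9, 40.0], [-179.9, 50.2]]]}},
    {"type": "Feature",
     "properties": {"label": "GA", "name": "Gulf of Alaska"},
     "geometry": {"type": "Polygon", "coordinates": [[
       [-155.0, 60.0], [-130.0, 60.0], [-130.0, 50.5], [-140.0, 52.0],
       [-155.0, 56.5], [-155.0, 60.0]]]}},
    {"type": "Feature",
     "properties": {"label": "CC", "name": "California Current"},
     "geometry": {"type": "Polygon", "coordinates": [[
       [-130.0, 48.5], [-116.0, 48.5], [-116.0, 30.0], [-130.0, 30.0],
       [-130.0, 48.5]]]}}
  ]
}
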