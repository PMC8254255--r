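<?xml version="1.0" encoding="UTF-8"?>
<graphml xmlns="http://graphml.graphdrawing.org/xmlns">
  <key id="v_name" for="node" attr.name="name" attr.type="string"/>
  <key id="v_x" for="node" attr.name="x" attr.type="double"/>
  <key id="v_y" for="node" attr.name="y" attr.type="double"/>
  <key id="e_length_km" for="edge" attr.name="length_km" attr.type="double"/>
  <key id="e_category" for="edge" attr.name="category" attr.type="string"/>
  <key id="e_urban" for="edge" attr.name="urban" attr.type="boolean"/>
  <graph id="G" edgedefault="undirected">
    <node id="n1">
      <data key="v_name">n1</data>
      <data key="v_x">0</data>
      <data key="v_y">0</data>
    </node>
    <node id="n2">
      <data key="v_name">n2</data>
      <data key="v_x">6</data>
      <data key="v_y">0</data>
    </node>
    <node id="n3">
      <data key="v_name">n3</data>
      <data key="v_x">6</data>
      <data key="v_y">5</data>
    </node>
    <edge source="n1" target="n2">
      <data key="e_length_km">7.2</data>
      <data key="e_category">national</data>
      <data key="e_urban">false</data>
    </edge>
    <edge source="n2" target="n3">
      <data key="e_length_km">5.6</data>
      <data key="e_category">local</data>
      <data key="e_urban">false</data>
    </edge>
  </graph>
</graphml>
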