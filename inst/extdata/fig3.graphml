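<?xml version="1.0" encoding="UTF-8"?>
<graphml xmlns="http://graphml.graphdrawing.org/xmlns"
         xmlns:xsi="http://www.w3.org/2001/XMLSchema-instance"
         xsi:schemaLocation="http://graphml.graphdrawing.org/xmlns
         http://graphml.graphdrawing.org/xmlns/1.0/graphml.xsd">
<!-- Created by igraph -->
  <key id="g_floor_height" for="graph" attr.name="floor_height" attr.type="double"/>
  <key id="g_start" for="graph" attr.name="start" attr.type="string"/>
  <key id="g_door_visibility" for="graph" attr.name="door_visibility" attr.type="string"/>
  <key id="v_name" for="node" attr.name="name" attr.type="string"/>
  <key id="v_label" for="node" attr.name="label" attr.type="string"/>
  <key id="v_floor" for="node" attr.name="floor" attr.type="double"/>
  <key id="v_block" for="node" attr.name="block" attr.type="string"/>
  <key id="v_x" for="node" attr.name="x" attr.type="double"/>
  <key id="v_y" for="node" attr.name="y" attr.type="double"/>
  <key id="v_category" for="node" attr.name="category" attr.type="string"/>
  <key id="v_corner" for="node" attr.name="corner" attr.type="boolean"/>
  <key id="e_link_type" for="edge" attr.name="link_type" attr.type="string"/>
  <graph id="G" edgedefault="undirected">
    <data key="g_floor_height">4</data>
    <data key="g_start">A</data>
    <data key="g_door_visibility"></data>
    <node id="n0">
      <data key="v_name">A</data>
      <data key="v_label">Corridor A</data>
      <data key="v_floor">0</data>
      <data key="v_block">NA</data>
      <data key="v_x">0</data>
      <data key="v_y">0</data>
      <data key="v_category">corridor</data>
      <data key="v_corner">false</data>
    </node>
    <node id="n1">
      <data key="v_name">B</data>
      <data key="v_label">Corridor B</data>
      <data key="v_floor">0</data>
      <data key="v_block">NA</data>
      <data key="v_x">4</data>
      <data key="v_y">0</data>
      <data key="v_category">corridor</data>
      <data key="v_corner">false</data>
    </node>
    <node id="n2">
      <data key="v_name">C</data>
      <data key="v_label">Room C</data>
      <data key="v_floor">0</data>
      <data key="v_block">NA</data>
      <data key="v_x">8</data>
      <data key="v_y">3</data>
      <data key="v_category">room</data>
      <data key="v_corner">false</data>
    </node>
    <node id="n3">
      <data key="v_name">D</data>
      <data key="v_label">Room D</data>
      <data key="v_floor">0</data>
      <data key="v_block">NA</data>
      <data key="v_x">8</data>
      <data key="v_y">-3</data>
      <data key="v_category">room</data>
      <data key="v_corner">false</data>
    </node>
    <node id="n4">
      <data key="v_name">E</data>
      <data key="v_label">Room E</data>
      <data key="v_floor">0</data>
      <data key="v_block">NA</data>
      <data key="v_x">8</data>
      <data key="v_y">0</data>
      <data key="v_category">room</data>
      <data key="v_corner">false</data>
    </node>
    <edge source="n0" target="n1">
      <data key="e_link_type">corridor</data>
    </edge>
    <edge source="n1" target="n2">
      <data key="e_link_type">door</data>
    </edge>
    <edge source="n1" target="n3">
      <data key="e_link_type">door</data>
    </edge>
    <edge source="n1" target="n4">
      <data key="e_link_type">door</data>
    </edge>
  </graph>
</graphml>
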