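<?xml version="1.0" encoding="UTF-8"?>
<pnml xmlns="http://www.pnml.org/version-2009/grammar/pnml">
  <net id="net1" type="http://www.pnml.org/version-2009/grammar/ptnet">
    <page id="page1">
      <place id="sucrose">
        <name><text>Sucrose</text></name>
      </place>
      <place id="glucose">
        <name><text>Glucose</text></name>
      </place>
      <place id="fructose">
        <name><text>Fructose</text></name>
      </place>
      <place id="F6P">
        <name><text>Fructose 6-phosphate</text></name>
      </place>
      <place id="G6P">
        <name><text>Glucose 6-phosphate</text></name>
      </place>
      <place id="starch">
        <name><text>Starch</text></name>
      </place>
      <place id="ADP">
        <name><text>ADP</text></name>
      </place>
      <place id="ATP">
        <name><text>ATP</text></name>
      </place>
      <transition id="invertase">
        <name><text>Invertase</text></name>
      </transition>
      <transition id="hexokinase">
        <name><text>Hexokinase</text></name>
      </transition>
      <transition id="fructokinase">
        <name><text>Fructokinase</text></name>
      </transition>
      <transition id="PGI_f">
        <name><text>Phosphoglucoisomerase (forward)</text></name>
        <toolspecific tool="petrinetr" version="0.1"><reverseOf>PGI_b</reverseOf></toolspecific>
      </transition>
      <transition id="PGI_b">
        <name><text>Phosphoglucoisomerase (backward)</text></name>
        <toolspecific tool="petrinetr" version="0.1"><reverseOf>PGI_f</reverseOf></toolspecific>
      </transition>
      <transition id="glycolysis">
        <name><text>Glycolysis</text></name>
      </transition>
      <transition id="starch_synthase">
        <name><text>Starch synthase</text></name>
      </transition>
      <transition id="sucrose_input">
        <name><text>Sucrose input</text></name>
      </transition>
      <transition id="starch_output">
        <name><text>Starch output</text></name>
      </transition>
      <arc id="a1" source="sucrose" target="invertase">
      </arc>
      <arc id="a2" source="invertase" target="glucose">
      </arc>
      <arc id="a3" source="invertase" target="fructose">
      </arc>
      <arc id="a4" source="glucose" target="hexokinase">
      </arc>
      <arc id="a5" source="ATP" target="hexokinase">
      </arc>
      <arc id="a6" source="hexokinase" target="G6P">
      </arc>
      <arc id="a7" source="hexokinase" target="ADP">
      </arc>
      <arc id="a8" source="fructose" target="fructokinase">
      </arc>
      <arc id="a9" source="ATP" target="fructokinase">
      </arc>
      <arc id="a10" source="fructokinase" target="F6P">
      </arc>
      <arc id="a11" source="fructokinase" target="ADP">
      </arc>
      <arc id="a12" source="G6P" target="PGI_f">
      </arc>
      <arc id="a13" source="PGI_f" target="F6P">
      </arc>
      <arc id="a14" source="F6P" target="PGI_b">
      </arc>
      <arc id="a15" source="PGI_b" target="G6P">
      </arc>
      <arc id="a16" source="F6P" target="glycolysis">
      </arc>
      <arc id="a17" source="ADP" target="glycolysis">
        <inscription><text>29</text></inscription>
      </arc>
      <arc id="a18" source="glycolysis" target="ATP">
        <inscription><text>29</text></inscription>
      </arc>
      <arc id="a19" source="G6P" target="starch_synthase">
      </arc>
      <arc id="a20" source="ATP" target="starch_synthase">
      </arc>
      <arc id="a21" source="starch_synthase" target="starch">
      </arc>
      <arc id="a22" source="starch_synthase" target="ADP">
      </arc>
      <arc id="a23" source="sucrose_input" target="sucrose">
      </arc>
      <arc id="a24" source="starch" target="starch_output">
      </arc>
    </page>
  </net>
</pnml>
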