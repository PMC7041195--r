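<?xml version="1.0" encoding="UTF-8"?>
<!-- SBML Level 3 + FBC v2 rendering of the TOY-B branched toy network.
     The boundary species A_ext exercises boundary-metabolite exclusion;
     R2b carries INF/-INF bounds to exercise bound capping. -->
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core"
      xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2"
      level="3" version="1" fbc:required="false">
  <model id="toyb" name="TOY-B branched network" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" constant="true"/>
      <compartment id="e" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="A_ext" compartment="e" boundaryCondition="true"
               hasOnlySubstanceUnits="false" constant="false"/>
      <species id="A" compartment="c" boundaryCondition="false"
               hasOnlySubstanceUnits="false" constant="false"/>
      <species id="B" compartment="c" boundaryCondition="false"
               hasOnlySubstanceUnits="false" constant="false"/>
      <species id="C" compartment="c" boundaryCondition="false"
               hasOnlySubstanceUnits="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="zero" value="0" constant="true"/>
      <parameter id="ten" value="10" constant="true"/>
      <parameter id="thousand" value="1000" constant="true"/>
      <parameter id="plus_inf" value="INF" constant="true"/>
      <parameter id="minus_inf" value="-INF" constant="true"/>
    </listOfParameters>
    <listOfReactions>
      <reaction id="EX_glc" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="ten">
        <listOfReactants>
          <speciesReference species="A_ext" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R1" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="thousand">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R2" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="thousand">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="R2b" reversible="true" fast="false"
                fbc:lowerFluxBound="minus_inf" fbc:upperFluxBound="plus_inf">
        <listOfReactants>
          <speciesReference species="A" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfProducts>
      </reaction>
      <reaction id="EX_bio" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="thousand">
        <listOfReactants>
          <speciesReference species="B" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="EX_prod" reversible="false" fast="false"
                fbc:lowerFluxBound="zero" fbc:upperFluxBound="thousand">
        <listOfReactants>
          <speciesReference species="C" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="EX_bio" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
  </model>
</sbml>
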