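<?xml version="1.0" encoding="UTF-8"?>
<COCHRANE_REVIEW REVIEW_ID="SR0001" VERSION="5.3">
  <COVER_SHEET>
    <TITLE>olanzapine versus placebo for schizophrenia</TITLE>
  </COVER_SHEET>
  <STUDIES_AND_REFERENCES>
    <STUDIES>
      <INCLUDED_STUDIES>
        <STUDY ID="Petrov 2004" NAME="Petrov 2004">
          <REFERENCE ID="REF-Petrov-2004-1">
            <TI>Report 1 of trial Petrov 2004</TI>
            <YR>2004</YR>
          </REFERENCE>
          <REFERENCE ID="REF-Petrov-2004-2">
            <TI>Report 2 of trial Petrov 2004</TI>
            <SO>J Clin Psychiatry</SO>
            <YR>2007</YR>
          </REFERENCE>
          <REFERENCE ID="REF-Petrov-2004-3">
            <TI>Report 3 of trial Petrov 2004</TI>
            <SO>Schizophr Res</SO>
            <YR>2007</YR>
          </REFERENCE>
        </STUDY>
        <STUDY ID="Urbina 2006" NAME="Urbina 2006">
          <REFERENCE ID="REF-Urbina-2006-1">
            <TI>Report 1 of trial Urbina 2006</TI>
            <SO>J Clin Psychiatry</SO>
            <YR>2006</YR>
          </REFERENCE>
          <REFERENCE ID="REF-Urbina-2006-2">
            <TI>Report 2 of trial Urbina 2006</TI>
            <YR>2007</YR>
          </REFERENCE>
          <REFERENCE ID="REF-Urbina-2006-3">
            <TI>Report 3 of trial Urbina 2006</TI>
            <YR>2008</YR>
          </REFERENCE>
        </STUDY>
      </INCLUDED_STUDIES>
    </STUDIES>
  </STUDIES_AND_REFERENCES>
  <CHARACTERISTICS_OF_STUDIES>
    <CHARACTERISTICS_OF_INCLUDED_STUDIES>
      <INCLUDED_CHAR STUDY_ID="Petrov 2004">
        <CHAR_METHODS>
          <P>Allocation: randomized. Blinding: open-label. Duration: 8 weeks.</P>
        </CHAR_METHODS>
        <CHAR_PARTICIPANTS>
          <P>N=16 inpatients with schizophrenia. Mean age 38 years.</P>
        </CHAR_PARTICIPANTS>
        <CHAR_INTERVENTIONS>
          <P>1. amisulpride: dose 530 mg/day. 2. Placebo.</P>
        </CHAR_INTERVENTIONS>
        <CHAR_OUTCOMES>
          <P>Clinical response, adverse effects and service outcomes reported.</P>
        </CHAR_OUTCOMES>
        <CHAR_NOTES>
          <P>Funding: public.</P>
        </CHAR_NOTES>
      </INCLUDED_CHAR>
      <INCLUDED_CHAR STUDY_ID="Urbina 2006">
        <CHAR_METHODS>
          <P>Allocation: randomized. Blinding: double-blind. Duration: 12 weeks.</P>
        </CHAR_METHODS>
        <CHAR_PARTICIPANTS>
          <P>N=60 inpatients with schizophrenia. Mean age 33 years.</P>
        </CHAR_PARTICIPANTS>
        <CHAR_INTERVENTIONS>
          <P>1. quetiapine: dose 480 mg/day. 2. Placebo.</P>
        </CHAR_INTERVENTIONS>
        <CHAR_OUTCOMES>
          <P>Clinical response, adverse effects and service outcomes reported.</P>
        </CHAR_OUTCOMES>
      </INCLUDED_CHAR>
    </CHARACTERISTICS_OF_INCLUDED_STUDIES>
  </CHARACTERISTICS_OF_STUDIES>
  <QUALITY_ITEMS>
    <QUALITY_ITEM NAME="Allocation concealment">
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Petrov 2004" RESULT="LOW">
        <DESCRIPTION>Quote: 'allocation concealment procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Urbina 2006" RESULT="UNCLEAR">
        <DESCRIPTION>Quote: 'allocation concealment procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
    </QUALITY_ITEM>
    <QUALITY_ITEM NAME="Selective reporting">
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Petrov 2004" RESULT="LOW">
        <DESCRIPTION>Quote: 'selective reporting procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
    </QUALITY_ITEM>
    <QUALITY_ITEM NAME="Random sequence generation">
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Petrov 2004" RESULT="UNCLEAR">
        <DESCRIPTION>Quote: 'random sequence generation procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
    </QUALITY_ITEM>
    <QUALITY_ITEM NAME="Incomplete outcome data">
      <QUALITY_ITEM_DATA_ENTRY STUDY_ID="Urbina 2006" RESULT="LOW">
        <DESCRIPTION>Quote: 'incomplete outcome data procedure described'.</DESCRIPTION>
      </QUALITY_ITEM_DATA_ENTRY>
    </QUALITY_ITEM>
  </QUALITY_ITEMS>
  <ANALYSES_AND_DATA>
    <COMPARISON ID="SR0001.CMP01" NAME="aripiprazole versus placebo">
      <DICH_OUTCOME ID="SR0001.CMP01.O001" NAME="Adverse effects: extrapyramidal symptoms.">
        <DICH_DATA STUDY_ID="Petrov 2004" EVENTS_1="44" TOTAL_1="50" EVENTS_2="20" TOTAL_2="27"/>
        <DICH_DATA STUDY_ID="Urbina 2006" EVENTS_1="14" TOTAL_1="36" EVENTS_2="24" TOTAL_2="28"/>
      </DICH_OUTCOME>
    </COMPARISON>
    <COMPARISON ID="SR0001.CMP02" NAME="haloperidol versus placebo">
      <DICH_OUTCOME ID="SR0001.CMP02.O001" NAME="Adverse effects: anticholinergic.">
        <DICH_DATA STUDY_ID="Petrov 2004" EVENTS_1="9" TOTAL_1="43" EVENTS_2="23" TOTAL_2="25"/>
      </DICH_OUTCOME>
      <DICH_OUTCOME ID="SR0001.CMP02.O002" NAME="Mental state: positive symptoms">
        <DICH_DATA STUDY_ID="Petrov 2004" EVENTS_1="4" TOTAL_1="57" EVENTS_2="4" TOTAL_2="25"/>
        <DICH_DATA STUDY_ID="Urbina 2006" EVENTS_1="6" TOTAL_1="35" EVENTS_2="28" TOTAL_2="42"/>
      </DICH_OUTCOME>
      <DICH_OUTCOME ID="SR0001.CMP02.O003" NAME="Adverse effects: seizures">
        <DICH_DATA STUDY_ID="Petrov 2004" EVENTS_1="4" TOTAL_1="34" EVENTS_2="31" TOTAL_2="40"/>
        <DICH_DATA STUDY_ID="Urbina 2006" EVENTS_1="9" TOTAL_1="59" EVENTS_2="24" TOTAL_2="55"/>
      </DICH_OUTCOME>
    </COMPARISON>
    <COMPARISON ID="SR0001.CMP03" NAME="clozapine versus placebo">
      <DICH_OUTCOME ID="SR0001.CMP03.O001" NAME="Global state: clinically important change">
        <DICH_DATA STUDY_ID="Petrov 2004" EVENTS_1="21" TOTAL_1="37" EVENTS_2="27" TOTAL_2="39"/>
        <DICH_DATA STUDY_ID="Urbina 2006" EVENTS_1="17" TOTAL_1="52" EVENTS_2="13" TOTAL_2="47"/>
      </DICH_OUTCOME>
      <DICH_OUTCOME ID="SR0001.CMP03.O002" NAME="Insight.">
        <DICH_DATA STUDY_ID="Urbina 2006" EVENTS_1="24" TOTAL_1="36" EVENTS_2="1" TOTAL_2="28"/>
      </DICH_OUTCOME>
      <CONT_OUTCOME ID="SR0001.CMP03.O003" NAME="Satisfaction with treatment">
        <CONT_DATA STUDY_ID="Urbina 2006" MEAN_1="55.159999999999997" SD_1="8.0800000000000001" TOTAL_1="37" MEAN_2="30.710000000000001" SD_2="14.08" TOTAL_2="47"/>
      </CONT_OUTCOME>
      <DICH_OUTCOME ID="SR0001.CMP03.O004" NAME="mental state: anxiety">
        <DICH_DATA STUDY_ID="Petrov 2004" EVENTS_1="14" TOTAL_1="29" EVENTS_2="9" TOTAL_2="43"/>
        <DICH_DATA STUDY_ID="Urbina 2006" EVENTS_1="38" TOTAL_1="48" EVENTS_2="19" TOTAL_2="33"/>
      </DICH_OUTCOME>
    </COMPARISON>
  </ANALYSES_AND_DATA>
</COCHRANE_REVIEW>
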